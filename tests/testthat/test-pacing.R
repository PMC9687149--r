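test_that("the default descending schedule matches the clinical protocol", {
  sch <- build_schedule()
  expect_equal(sch$cycle_lengths[1], 750)
  expect_equal(tail(sch$cycle_lengths, 1), 180)
  expect_length(sch$cycle_lengths, 26)
  expect_true(all(diff(sch$cycle_lengths) < 0))
  expect_equal(sch$beats_per_cl, 74)
  expect_equal(sch$cycle_lengths,
               c(seq(750, 350, -50), seq(340, 180, -10)))
  expect_error(build_schedule(start_cl = 300), "start_cl > switch_cl")
  expect_error(build_schedule(coarse_step = -50), "steps")
})

test_that("steady-state pacing converges and is bitwise reproducible", {
  g <- default_conductances()
  st1 <- cached("ss750", steady_state_init(g, 750))
  st2 <- steady_state_init(g, 750)
  expect_identical(as.numeric(st1), as.numeric(st2))
  expect_true(attr(st1, "beats_used") <= 200)
  expect_no_error(alternanspop:::.validate_state(st1))
  # pacing one further beat changes any state variable only a little
  cfg <- integrator_config()
  nxt <- alternanspop:::tt_pace_cpp(as.numeric(st1),
                                    alternanspop:::.as_params(g), 750, 1,
                                    cfg$dt, cfg$stim_amplitude,
                                    cfg$stim_duration, -1, 0)$state
  expect_lt(max(abs(nxt - as.numeric(st1)) /
                pmax(abs(as.numeric(st1)), 1e-6)), 5e-3)
})

test_that("protocol runs carry state continuously across cycle lengths", {
  g <- default_conductances()
  st <- cached("ss750", steady_state_init(g, 750))
  sch <- short_schedule()
  run <- run_protocol(g, sch, init_state = st)
  expect_equal(run$cycle_lengths, sch$cycle_lengths)
  expect_equal(nrow(run$beats), length(sch$cycle_lengths) * sch$beats_per_cl)
  # stimulus spacing equals the current cycle length within each stage
  for (cl in sch$cycle_lengths) {
    stim <- run$beats$stim_time[run$beats$cl_ms == cl]
    expect_equal(diff(stim), rep(cl, sch$beats_per_cl - 1))
  }
  # stage boundaries are contiguous in absolute time
  expect_equal(min(run$beats$stim_time[run$beats$cl_ms == 350]),
               max(run$beats$stim_time[run$beats$cl_ms == 400]) + 400)
  # continuity: re-running the first stage alone lands on the same state
  cfg <- integrator_config()
  stage1 <- alternanspop:::tt_pace_cpp(as.numeric(st),
                                       alternanspop:::.as_params(g), 400,
                                       sch$beats_per_cl, cfg$dt,
                                       cfg$stim_amplitude,
                                       cfg$stim_duration, -1, 0)
  stage2 <- alternanspop:::tt_pace_cpp(stage1$state,
                                       alternanspop:::.as_params(g), 350,
                                       sch$beats_per_cl, cfg$dt,
                                       cfg$stim_amplitude,
                                       cfg$stim_duration, -1, 0)
  b2 <- run$beats[run$beats$cl_ms == 350, ]
  expect_equal(b2$apd90, unname(stage2$beats[, "apd90"]))
})

test_that("identical configuration reproduces the protocol run exactly", {
  g <- default_conductances()
  st <- cached("ss750", steady_state_init(g, 750))
  sch <- build_schedule(start_cl = 500, coarse_step = 50, switch_cl = 400,
                        fine_step = 50, end_cl = 350, beats_per_cl = 5)
  r1 <- run_protocol(g, sch, init_state = st)
  r2 <- run_protocol(g, sch, init_state = st)
  expect_identical(r1$beats, r2$beats)
  expect_identical(as.numeric(r1$final_state), as.numeric(r2$final_state))
})

test_that("trace storage rate does not limit APD90 accuracy", {
  g <- default_conductances()
  st <- cached("ss750", steady_state_init(g, 750))
  sch <- build_schedule(start_cl = 600, coarse_step = 50, switch_cl = 550,
                        fine_step = 10, end_cl = 540, beats_per_cl = 3)
  r1 <- run_protocol(g, sch, init_state = st, store_traces = TRUE,
                     trace_dt = 0.1)
  r2 <- run_protocol(g, sch, init_state = st, store_traces = TRUE,
                     trace_dt = 0.05)
  for (cl in names(r1$traces)) {
    b <- r1$beats[r1$beats$cl_ms == as.numeric(cl), ]
    a1 <- beats_from_trace(r1$traces[[cl]]$t, r1$traces[[cl]]$vm,
                           b$stim_time)$apd90
    a2 <- beats_from_trace(r2$traces[[cl]]$t, r2$traces[[cl]]$vm,
                           b$stim_time)$apd90
    expect_lt(max(abs(a1 - a2)), 0.2)
    # trace-derived APD90s agree with the integrator-resolution records
    expect_lt(max(abs(a1 - b$apd90)), 0.2)
  }
})
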