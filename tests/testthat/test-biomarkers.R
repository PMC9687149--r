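test_that("APD90 is recovered from analytic action-potential templates", {
  # planted APD90 of 200 ms, clean sampling
  tr <- synth_ap_train(apds = rep(200, 3), cl = 500)
  for (b in 1:3) {
    a <- apd90(tr$time, tr$vm, stim_time = tr$stim_times[b],
               window_end = tr$stim_times[b] + 500)
    expect_lt(abs(a - 200), 0.5)
  }

  # an idealized square pulse of width w has APD90 = w up to one sample
  t <- seq(0, 400, by = 0.1)
  v <- ifelse(t >= 10 & t < 160, 20, -80)
  expect_lt(abs(apd90(t, v, stim_time = 10) - 150), 0.1 + 1e-9)

  # the threshold is amplitude-relative: voltage offsets change nothing
  tr2 <- synth_ap_train(apds = 180, cl = 400)
  a0 <- apd90(tr2$time, tr2$vm, 0)
  a1 <- apd90(tr2$time, tr2$vm + 17.3, 0)
  expect_equal(a0, a1)

  # no repolarization crossing inside the window -> NA with a warning
  expect_warning(
    out <- apd90(tr2$time[tr2$time < 100], tr2$vm[tr2$time < 100], 0),
    "crossing")
  expect_true(is.na(out))
})

test_that("alternans magnitude follows its defining arithmetic", {
  expect_equal(alternans_magnitude(rep(250, 11)), 0)
  alt <- rep(c(210, 190), length.out = 11)
  expect_equal(alternans_magnitude(alt), 20)
  alt2 <- rep(c(66.3, 48.8), length.out = 11)
  expect_equal(alternans_magnitude(alt2), 17.5)
  expect_error(alternans_magnitude(rep(200, 10)), "11")
  expect_error(alternans_magnitude(c(rep(200, 10), NA)), "finite")
})

test_that("normalized alternans magnitude is scale invariant", {
  expect_equal(anm(rep(250, 11)), 0)
  set.seed(7)
  for (i in 1:25) {
    apds <- runif(11, 100, 400)
    a <- anm(apds)
    expect_gte(a, 0)
    c <- runif(1, 0.1, 10)
    expect_equal(anm(c * apds), a, tolerance = 1e-12)
  }
})

test_that("alternans classification is strict at the threshold", {
  expect_false(classify_alternans(0.0455))
  expect_true(classify_alternans(0.0553))
  expect_false(classify_alternans(0.05))
  expect_error(classify_alternans(-0.1), "non-negative")
})

test_that("scenario summary scans the schedule from longest cycle length", {
  # no alternans anywhere: onset biomarkers are (0, 0)
  quiet <- fake_run(list(`750` = rep(300, 74), `700` = rep(290, 74)))
  s <- summarize_scenario(quiet)
  expect_equal(s$aocl_ms, 0)
  expect_equal(s$ao_mean_apd_ms, 0)
  expect_equal(s$quality, "ok")

  # a single alternans-positive cycle length pins the onset
  alt <- rep(c(320, 260), length.out = 74)
  r2 <- fake_run(list(`750` = rep(300, 74), `600` = rep(295, 74),
                      `550` = alt, `500` = rep(200, 74)))
  s2 <- summarize_scenario(r2)
  expect_equal(s2$aocl_ms, 550)
  expect_equal(s2$ao_mean_apd_ms, mean(tail(alt, 10)))
  expect_true(s2$per_cl$alternans[s2$per_cl$cl_ms == 550])

  # incomplete-capture cycle lengths are excluded and flag the scenario
  r3 <- fake_run(list(`750` = rep(300, 74), `700` = alt),
                 capture = list(rep(1, 74), c(rep(1, 70), 0, 1, 1, 1)))
  s3 <- summarize_scenario(r3)
  expect_equal(s3$quality, "incomplete_capture")
  expect_equal(s3$aocl_ms, 0)

  # nothing complete: flagged, not silently zero
  r4 <- fake_run(list(`750` = rep(NA_real_, 74)),
                 capture = list(rep(0, 74)))
  s4 <- summarize_scenario(r4)
  expect_equal(s4$quality, "no_complete_cls")
  expect_true(is.na(s4$aocl_ms))
})

test_that("onset cycle length is always on the schedule or zero", {
  sch <- build_schedule()
  set.seed(11)
  for (i in 1:10) {
    cls <- sort(sample(sch$cycle_lengths, 6), decreasing = TRUE)
    apds <- lapply(cls, function(cl) {
      base <- runif(1, 150, 300)
      if (runif(1) < 0.4) rep(c(base + 20, base - 20), length.out = 74)
      else rep(base, 74)
    })
    names(apds) <- cls
    s <- summarize_scenario(fake_run(apds))
    expect_true(s$aocl_ms %in% c(0, cls))
    expect_equal(s$aocl_ms == 0, s$ao_mean_apd_ms == 0)
  }
})

test_that("restitution curves report planted linear slopes", {
  cls <- seq(750, 350, -50)
  apds <- lapply(cls, function(cl) rep(100 + 0.25 * cl, 74))
  names(apds) <- cls
  rc <- restitution_curve(fake_run(apds))
  expect_equal(nrow(rc), length(cls))
  expect_equal(rc$slope[-1], rep(0.25, length(cls) - 1), tolerance = 1e-10)
})

test_that("the simulated myocyte shows conventional restitution", {
  # meanAPD decreases with cycle length over the coarse stages
  g <- default_conductances()
  st <- cached("ss750", steady_state_init(g, 750))
  sch <- build_schedule(start_cl = 750, coarse_step = 175, switch_cl = 400,
                        fine_step = 50, end_cl = 350, beats_per_cl = 12)
  run <- run_protocol(g, sch, init_state = st)
  rc <- restitution_curve(run)
  # ordered by decreasing cycle length; the baseline restitution of this
  # parameterization is shallow, so compare across the full span
  expect_lt(rc$mean_apd_ms[3], rc$mean_apd_ms[1])
  expect_lt(rc$mean_apd_ms[4], rc$mean_apd_ms[1])
})
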