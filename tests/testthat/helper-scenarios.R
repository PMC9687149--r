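# Shared fixtures and memoized heavy runs (one protocol run per worked
# scenario, reused across test blocks in the session).

# keep the progress reporter from aborting the whole run on accumulated
# failures; every file should execute
options(testthat.progress.max_fails = 1000)

.cache <- new.env(parent = emptyenv())

# scenario codes of the worked examples: levels in channel order
# (g_Ks, g_Kr, g_K1, g_Na, g_bNa, g_CaL, g_bCa, g_to, g_pCa, g_pK)
scenario_levels <- function(up) {
  code <- rep(0.5, 10)
  names(code) <- channel_names()
  code[up] <- 1.5
  code
}
code_max_ao   <- scenario_levels(c("g_CaL", "g_bCa"))
code_min_ao   <- scenario_levels(c("g_bNa", "g_CaL", "g_bCa", "g_pK"))
code_min_apd  <- scenario_levels(c("g_Kr", "g_K1", "g_bNa", "g_CaL",
                                   "g_bCa", "g_to", "g_pK"))

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- expr
  .cache[[key]]
}

cached_run <- function(key, code, ...) {
  if (is.null(.cache[[key]])) {
    g <- apply_scenario(default_conductances(), code)
    .cache[[key]] <- run_protocol(g, early_stop = TRUE, code = code, ...)
  }
  .cache[[key]]
}

# a short, fast schedule for structural pacing tests
short_schedule <- function() build_schedule(start_cl = 400, coarse_step = 50,
                                            switch_cl = 350, fine_step = 10,
                                            end_cl = 340, beats_per_cl = 12)

# build a synthetic protocol_run object with planted per-beat APDs, for
# testing the summary logic independently of the ODE model
fake_run <- function(apds_by_cl, beats_per_cl = 74, capture = NULL,
                     anm_threshold = 0.05) {
  cls <- as.numeric(names(apds_by_cl))
  beats <- do.call(rbind, lapply(seq_along(cls), function(i) {
    apds <- apds_by_cl[[i]]
    n <- length(apds)
    cap <- if (is.null(capture)) rep(1, n) else capture[[i]]
    data.frame(cl_ms = cls[i], beat = seq_len(n),
               stim_time = (seq_len(n) - 1) * cls[i],
               t_upstroke = (seq_len(n) - 1) * cls[i] + 1,
               peak_vm = ifelse(cap == 1, 30, -40), rest_vm = -85,
               apd90 = apds, capture = cap)
  }))
  structure(list(code = NULL, beats = beats, cycle_lengths = cls,
                 beats_per_cl = beats_per_cl, final_state = NULL,
                 traces = NULL, early_stopped = FALSE,
                 anm_threshold = anm_threshold,
                 failed = FALSE, failure = NULL),
            class = "protocol_run")
}
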