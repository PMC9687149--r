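# Seed-deterministic synthetic generators with known ground truth: analytic
# action-potential trains for the biomarker pipeline, planted separable
# scalar fields for the stacking optimizer, and planted summary tables for
# the aggregate statistics. The AP template is analytic (not ODE-derived) so
# biomarker tests are independent of the ionic model.

#' Synthetic paced action-potential train with planted APD90s
#'
#' Builds a piecewise analytic AP template per beat: a linear fast upstroke
#' from the resting to the peak potential, a plateau, and a logistic
#' repolarization whose 90% crossing is placed analytically so that the
#' beat's APD90 (measured from the maximum upstroke) equals the planted
#' value.
#'
#' @param apds Per-beat APD90 sequence, ms (each < `cl`).
#' @param cl Cycle length, ms.
#' @param rest_mv,peak_mv Resting and peak potential, mV.
#' @param upstroke_ms Upstroke duration, ms.
#' @param shape_ms Logistic repolarization time constant, ms (reduced
#'   automatically for very short APDs).
#' @param sample_ms Sampling interval, ms.
#' @param noise_sd Additive Gaussian noise, mV.
#' @param seed RNG seed (the trace is bitwise reproducible given the seed).
#' @return List with `time`, `vm`, `stim_times` and `truth` (data frame of
#'   planted per-beat upstroke times and APD90s).
#' @export
synth_ap_train <- function(apds, cl = 500, rest_mv = -85, peak_mv = 35,
                           upstroke_ms = 1, shape_ms = 8, sample_ms = 0.1,
                           noise_sd = 0, seed = 1L) {
  if (any(apds >= cl))
    stop("planted APDs must be shorter than the cycle length")
  if (sample_ms <= 0) stop("sampling interval must be > 0")
  nb <- length(apds)
  time <- seq(0, nb * cl - sample_ms, by = sample_ms)
  vm <- rep(rest_mv, length(time))
  amp <- peak_mv - rest_mv
  stim_times <- (seq_len(nb) - 1) * cl
  # the rise has constant (maximal) slope from the stimulus sample on, so the
  # detected upstroke time is the stimulus time itself
  t_up <- stim_times
  for (b in seq_len(nb)) {
    k <- min(shape_ms, apds[b] / 10)
    tl <- time - stim_times[b]
    in_beat <- tl >= 0 & tl < cl
    # 90% crossing of the logistic falls at t0 + k*log(9) after the upstroke
    t0 <- apds[b] - k * log(9)
    fall <- rest_mv + amp / (1 + exp((tl - t0) / k))
    # concave rise (maximal slope at onset) so the detected upstroke sample
    # is robust to additive noise
    rf <- (1 - exp(-4 * pmax(0, tl) / upstroke_ms)) / (1 - exp(-4))
    rise <- rest_mv + amp * pmin(1, pmax(0, rf))
    vm[in_beat] <- pmin(rise[in_beat], fall[in_beat])
  }
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           .GlobalEnv))
    set.seed(seed)
    vm <- vm + stats::rnorm(length(vm), 0, noise_sd)
  }
  truth <- data.frame(beat = seq_len(nb), stim_time = stim_times,
                      t_upstroke = t_up, apd90 = apds)
  list(time = time, vm = vm, stim_times = stim_times, truth = truth)
}

#' Planted separable scalar field on a factorial grid
#'
#' Generates `value(code) = sum_k w_k * f(level_k) + noise` over the full
#' `|levels|^d` factorial, so the ground-truth sensitivity ranking of the
#' channels is the ordering of `|w_k|`.
#'
#' @param weights Per-channel weights with distinct magnitudes (`d >= 2`).
#' @param level_effects Per-level effect values `f(level)`.
#' @param levels Ordered level set.
#' @param noise_sd Additive Gaussian noise.
#' @param seed RNG seed.
#' @return A sweep-table-shaped data frame: `scenario_id`, `level_ch*`
#'   columns and `value`, with attribute `ranking` (channel names by
#'   decreasing `|w|`).
#' @export
synth_scalar_field <- function(weights, level_effects = c(-1, 0, 1),
                               levels = c(0.5, 1.0, 1.5), noise_sd = 0,
                               seed = 1L) {
  d <- length(weights)
  if (d < 2) stop("need at least 2 channels")
  if (anyDuplicated(abs(weights)))
    stop("weights must have distinct magnitudes")
  codes <- enumerate_scenarios(d, levels)
  eff <- matrix(level_effects[match(codes, levels)], nrow = nrow(codes))
  value <- as.numeric(eff %*% weights)
  if (noise_sd > 0) {
    old_seed <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           .GlobalEnv))
    set.seed(seed)
    value <- value + stats::rnorm(length(value), 0, noise_sd)
  }
  tab <- data.frame(scenario_id = seq_len(nrow(codes)) - 1)
  lv <- as.data.frame(codes)
  names(lv) <- paste0("level_", colnames(codes))
  tab <- cbind(tab, lv)
  tab$value <- value
  attr(tab, "ranking") <- colnames(codes)[order(-abs(weights))]
  tab
}

#' Planted scenario-summary table
#'
#' Rows with AOCL drawn from the pacing schedule and
#' `AO meanAPD = slope * AOCL + intercept + noise`, plus a planted fraction
#' of non-alternans (0, 0) rows, for testing aggregate statistics with a
#' known correlation structure.
#'
#' @param n Number of rows (>= 2).
#' @param slope,intercept Linear AOCL to AO meanAPD relation.
#' @param noise_sd Gaussian noise on AO meanAPD, ms.
#' @param zero_frac Fraction of non-alternans rows (AOCL = AO meanAPD = 0).
#' @param schedule A `pacing_schedule` supplying the AOCL support.
#' @param seed RNG seed.
#' @return A minimal sweep table: `scenario_id`, `aocl_ms`,
#'   `ao_mean_apd_ms`, `quality`.
#' @export
synth_summary_table <- function(n, slope = 0.9, intercept = 0, noise_sd = 0,
                                zero_frac = 0, schedule = build_schedule(),
                                seed = 1L) {
  if (n < 2) stop("need n >= 2 rows")
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  n_zero <- round(zero_frac * n)
  aocl <- c(rep(0, n_zero),
            sample(schedule$cycle_lengths, n - n_zero, replace = TRUE))
  ao <- ifelse(aocl == 0, 0,
               slope * aocl + intercept + stats::rnorm(n, 0, noise_sd))
  data.frame(scenario_id = seq_len(n) - 1, aocl_ms = aocl,
             ao_mean_apd_ms = ao, quality = "ok")
}
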