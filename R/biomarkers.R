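# APD alternans biomarkers: APD90 from traces, alternans magnitude (AM),
# normalized alternans magnitude (ANM), alternans classification, and the
# per-scenario onset summary (AOCL, AO meanAPD).

#' APD90 of one beat from a membrane-potential trace
#'
#' The action potential duration at 90% repolarization: the time from the
#' maximum upstroke (maximum dVm/dt after the stimulus) to the linearly
#' interpolated instant Vm falls through `Vrest + 0.1 * (Vpeak - Vrest)`,
#' with `Vrest` the pre-stimulus potential and `Vpeak` the beat maximum. The
#' threshold is amplitude-relative, so a constant voltage offset leaves the
#' result unchanged.
#'
#' @param time Sample times, ms (uniform or not, strictly increasing).
#' @param vm Membrane potential samples, mV.
#' @param stim_time Stimulus time of the beat, ms; samples before it define
#'   the resting potential.
#' @param window_end End of the beat's analysis window (defaults to the last
#'   sample), ms.
#' @return APD90 in ms, or `NA` with a warning when the beat does not
#'   repolarize through the 90% threshold within the window (no capture or
#'   incomplete repolarization).
#' @export
apd90 <- function(time, vm, stim_time = time[1], window_end = max(time)) {
  keep <- time >= stim_time & time <= window_end
  t <- time[keep]; v <- vm[keep]
  if (length(t) < 3) stop("beat window contains fewer than 3 samples")
  pre <- vm[time < stim_time]
  rest <- if (length(pre)) pre[length(pre)] else v[1]
  dv <- diff(v) / diff(t)
  kup <- which.max(dv)
  t_up <- t[kup]
  kpk <- which.max(v)
  peak <- v[kpk]
  thr <- rest + 0.1 * (peak - rest)
  if (peak <= rest) { warning("no upstroke in beat window"); return(NA_real_) }
  vv <- v[kpk:length(v)]; tt <- t[kpk:length(t)]
  idx <- which(vv[-length(vv)] > thr & vv[-1] <= thr)
  if (!length(idx)) {
    warning("no 90% repolarization crossing within the beat window")
    return(NA_real_)
  }
  k <- idx[1]
  t_cross <- tt[k] + (tt[k + 1] - tt[k]) * (vv[k] - thr) / (vv[k] - vv[k + 1])
  t_cross - t_up
}

#' Per-beat records from a continuous trace
#'
#' Splits a paced trace at the given stimulus times and computes the per-beat
#' metrics used by the protocol driver: upstroke time, peak and resting Vm,
#' APD90 and a capture flag (peak above 0 mV).
#'
#' @param time,vm Trace samples (ms, mV).
#' @param stim_times Stimulus times delimiting the beats, ms.
#' @return Data frame with one row per beat: `beat`, `stim_time`,
#'   `t_upstroke`, `peak_vm`, `rest_vm`, `apd90`, `capture`.
#' @export
beats_from_trace <- function(time, vm, stim_times) {
  ends <- c(stim_times[-1], max(time))
  out <- lapply(seq_along(stim_times), function(i) {
    keep <- time >= stim_times[i] & time <= ends[i]
    t <- time[keep]; v <- vm[keep]
    rest <- v[1]
    kup <- which.max(diff(v) / diff(t))
    peak <- max(v)
    cap <- peak > 0
    apd <- if (cap)
      suppressWarnings(apd90(t, v, stim_time = stim_times[i])) else NA_real_
    data.frame(beat = i, stim_time = stim_times[i], t_upstroke = t[kup],
               peak_vm = peak, rest_vm = rest, apd90 = apd,
               capture = as.numeric(cap))
  })
  do.call(rbind, out)
}

#' Alternans magnitude (AM)
#'
#' The mean of the ten absolute successive APD90 differences over the last
#' eleven beats at one cycle length: `AM = mean(|m[i+1] - m[i]|)` for
#' `i = 1..10`. A constant train gives 0; a perfectly alternating train
#' `a, b, a, ...` gives `|a - b|`.
#'
#' @param apds The last 11 beat APD90s, ms.
#' @return AM in ms.
#' @export
alternans_magnitude <- function(apds) {
  if (length(apds) != 11 || any(!is.finite(apds)))
    stop("alternans magnitude needs exactly 11 finite APD values")
  mean(abs(diff(apds)))
}

#' Normalized alternans magnitude (ANM)
#'
#' The ratio of the alternans magnitude to the mean APD90 of the last ten
#' beats. ANM is dimensionless, non-negative and invariant to scaling all
#' APDs by a common positive factor.
#'
#' @param apds The last 11 beat APD90s, ms.
#' @return ANM (dimensionless).
#' @export
anm <- function(apds) {
  am <- alternans_magnitude(apds)
  m <- mean(utils::tail(apds, 10))
  if (m <= 0) stop("mean APD must be > 0")
  am / m
}

#' Classify APD alternans from an ANM value
#'
#' Alternans is declared when ANM strictly exceeds the threshold (default
#' 0.05); a value exactly at the threshold is not alternans.
#'
#' @param x ANM value(s), finite and non-negative.
#' @param threshold Classification threshold.
#' @return Logical vector.
#' @export
classify_alternans <- function(x, threshold = 0.05) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("ANM values must be finite and non-negative")
  x > threshold
}

#' Per-cycle-length alternans metrics of a protocol run
#'
#' For each executed cycle length: the mean APD90 of the last 10 beats, AM
#' and ANM from the last 11 beats, the alternans flag, and whether the cycle
#' length had complete 1:1 capture (every beat captured with a finite APD90).
#' Metrics are `NA` for incomplete cycle lengths.
#'
#' @param run A `protocol_run`.
#' @return Data frame with columns `cl_ms`, `mean_apd_ms`, `am_ms`, `anm`,
#'   `alternans`, `complete`.
#' @export
cycle_length_results <- function(run) {
  stopifnot(inherits(run, "protocol_run"))
  out <- lapply(run$cycle_lengths, function(cl) {
    b <- run$beats[run$beats$cl_ms == cl, ]
    complete <- nrow(b) >= 11 && all(b$capture == 1) && all(is.finite(b$apd90))
    if (complete) {
      apds <- utils::tail(b$apd90, 11)
      am <- alternans_magnitude(apds)
      m <- mean(utils::tail(apds, 10))
      a <- am / m
      data.frame(cl_ms = cl, mean_apd_ms = m, am_ms = am, anm = a,
                 alternans = classify_alternans(a, run$anm_threshold),
                 complete = TRUE)
    } else {
      data.frame(cl_ms = cl, mean_apd_ms = NA_real_, am_ms = NA_real_,
                 anm = NA_real_, alternans = NA, complete = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Scenario summary: alternans onset cycle length and onset meanAPD
#'
#' Scans the executed schedule from the longest to the shortest cycle length
#' and reports the first (longest) cycle length whose ANM exceeds the
#' threshold as the alternans onset cycle length (AOCL) and that cycle
#' length's mean APD90 as the onset meanAPD (AO meanAPD). Both are 0 when no
#' cycle length qualifies. Incomplete-capture cycle lengths are excluded from
#' the scan and flagged; if no cycle length is complete the summary is
#' quality-flagged rather than silently zero.
#'
#' @param run A `protocol_run`.
#' @return A list of class `scenario_summary`: `code`, `scenario_id`,
#'   `aocl_ms`, `ao_mean_apd_ms`, `per_cl` (the [cycle_length_results()]
#'   table) and `quality` (`"ok"`, `"incomplete_capture"`,
#'   `"no_complete_cls"` or `"failed"`).
#' @export
summarize_scenario <- function(run) {
  stopifnot(inherits(run, "protocol_run"))
  per_cl <- cycle_length_results(run)
  if (nrow(per_cl) < 1) stop("run has no executed cycle lengths")
  quality <- if (run$failed) "failed"
             else if (!any(per_cl$complete)) "no_complete_cls"
             else if (!all(per_cl$complete)) "incomplete_capture"
             else "ok"
  aocl <- 0
  ao <- 0
  if (any(per_cl$complete)) {
    cc <- per_cl[per_cl$complete, ]
    cc <- cc[order(-cc$cl_ms), ]
    hit <- which(cc$alternans)
    if (length(hit)) {
      aocl <- cc$cl_ms[hit[1]]
      ao <- cc$mean_apd_ms[hit[1]]
    }
  } else {
    aocl <- NA_real_
    ao <- NA_real_
  }
  structure(list(code = run$code,
                 scenario_id = if (!is.null(run$code))
                   scenario_index(run$code) else NA_integer_,
                 aocl_ms = aocl, ao_mean_apd_ms = ao,
                 per_cl = per_cl, quality = quality),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat("<scenario_summary> AOCL =", x$aocl_ms, "ms, AO meanAPD =",
      round(x$ao_mean_apd_ms, 1), "ms, quality =", x$quality, "\n")
  invisible(x)
}

#' APD restitution curve of a protocol run
#'
#' One (cycle length, meanAPD) point per complete-capture cycle length, plus
#' the finite-difference slope of meanAPD against cycle length between
#' adjacent schedule points.
#'
#' @param run A `protocol_run`.
#' @return Data frame with columns `cl_ms`, `mean_apd_ms`, `slope`.
#' @export
restitution_curve <- function(run) {
  per_cl <- cycle_length_results(run)
  cc <- per_cl[per_cl$complete, c("cl_ms", "mean_apd_ms")]
  cc <- cc[order(-cc$cl_ms), ]
  cc$slope <- c(NA_real_, diff(cc$mean_apd_ms) / diff(cc$cl_ms))
  rownames(cc) <- NULL
  cc
}
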