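# Descending cycle-length pacing: schedule construction, steady-state
# initialization and the full protocol driver.

#' Build the descending cycle-length schedule
#'
#' The clinical dynamic pacing protocol descends in coarse decrements down to
#' a switch point and then in fine decrements to the final cycle length; both
#' endpoints are included. The default schedule is 750 to 350 ms in 50 ms
#' steps followed by 340 to 180 ms in 10 ms steps (26 cycle lengths), with 74
#' paced beats per cycle length.
#'
#' @param start_cl First (longest) cycle length, ms.
#' @param coarse_step Decrement until `switch_cl`, ms.
#' @param switch_cl Cycle length at which the decrement changes, ms.
#' @param fine_step Decrement after `switch_cl`, ms.
#' @param end_cl Last (shortest) cycle length, ms.
#' @param beats_per_cl Number of paced beats per cycle length.
#' @return A list of class `pacing_schedule` with elements `cycle_lengths`
#'   (strictly decreasing) and `beats_per_cl`.
#' @export
build_schedule <- function(start_cl = 750, coarse_step = 50, switch_cl = 350,
                           fine_step = 10, end_cl = 180, beats_per_cl = 74) {
  if (!(start_cl > switch_cl && switch_cl > end_cl))
    stop("need start_cl > switch_cl > end_cl")
  if (coarse_step <= 0 || fine_step <= 0) stop("steps must be > 0")
  cls <- c(seq(start_cl, switch_cl, by = -coarse_step),
           seq(switch_cl - fine_step, end_cl, by = -fine_step))
  structure(list(cycle_lengths = cls, beats_per_cl = beats_per_cl),
            class = "pacing_schedule")
}

#' Pace to steady state at a fixed cycle length
#'
#' Paces the cell at `cl` until the maximum relative change of any state
#' variable, sampled at stimulus times between successive beats, falls below
#' `tol`, capped at `max_beats` beats.
#'
#' @param g A `conductance_set`.
#' @param cl Cycle length, ms.
#' @param cfg An `integrator_config`.
#' @param tol Relative convergence tolerance.
#' @param max_beats Beat cap.
#' @param init Starting `cell_state`; default [initial_state()].
#' @return The end `cell_state`, with attributes `beats_used` and
#'   `converged`.
#' @export
steady_state_init <- function(g, cl = 750, cfg = integrator_config(),
                              tol = 1e-4, max_beats = 200, init = NULL) {
  if (cl <= cfg$stim_duration) stop("cycle length must exceed the stimulus")
  if (is.null(init)) init <- initial_state()
  .validate_state(init)
  res <- tt_prepace_cpp(as.numeric(init), .as_params(g), cl, max_beats, tol,
                        cfg$dt, cfg$stim_amplitude, cfg$stim_duration)
  structure(stats::setNames(res$state, .state_names), class = "cell_state",
            time = 0, beats_used = res$beats_used,
            converged = res$converged)
}

#' Run the descending pacing protocol
#'
#' Drives the myocyte through every cycle length of the schedule, carrying
#' the cell state continuously across cycle lengths (no re-initialization),
#' and records per-beat metrics: stimulus time, upstroke time (maximum
#' dVm/dt), peak and pre-stimulus Vm, APD90 and a capture flag. With
#' `early_stop = TRUE` the run halts after the first cycle length classified
#' as alternans (ANM above `anm_threshold`), which is sufficient for AOCL and
#' onset-meanAPD biomarkers.
#'
#' @param g A `conductance_set` (typically from [apply_scenario()]).
#' @param schedule A `pacing_schedule`.
#' @param cfg An `integrator_config`.
#' @param init_state Starting state; default is [steady_state_init()] at the
#'   first scheduled cycle length.
#' @param early_stop Halt after the first alternans-positive cycle length.
#' @param store_traces Keep Vm traces (down-sampled to `trace_dt`).
#' @param trace_dt Trace sampling interval, ms.
#' @param anm_threshold Alternans classification threshold on ANM.
#' @param code Optional scenario code recorded in the result.
#' @param ss_tol,ss_max_beats Steady-state initialization tolerance and beat
#'   cap (see [steady_state_init()]); used only when `init_state` is `NULL`.
#' @return A list of class `protocol_run`: `beats` (data frame over all
#'   executed cycle lengths), `cycle_lengths` (those executed),
#'   `beats_per_cl`, `final_state`, `traces` (optional, one per cycle
#'   length), `early_stopped`, `failed`/`failure` annotations and `code`.
#' @export
run_protocol <- function(g, schedule = build_schedule(),
                         cfg = integrator_config(), init_state = NULL,
                         early_stop = FALSE, store_traces = FALSE,
                         trace_dt = 0.1, anm_threshold = 0.05, code = NULL,
                         ss_tol = 1e-4, ss_max_beats = 200) {
  if (is.null(init_state))
    init_state <- steady_state_init(g, schedule$cycle_lengths[1], cfg,
                                    tol = ss_tol, max_beats = ss_max_beats)
  .validate_state(init_state)
  p <- .as_params(g)
  state <- as.numeric(init_state)
  beats <- list()
  traces <- if (store_traces) list() else NULL
  t_off <- 0
  executed <- numeric(0)
  early_stopped <- FALSE
  failed <- FALSE
  failure <- NULL

  for (cl in schedule$cycle_lengths) {
    res <- tryCatch(
      tt_pace_cpp(state, p, cl, schedule$beats_per_cl, cfg$dt,
                  cfg$stim_amplitude, cfg$stim_duration,
                  if (store_traces) trace_dt else -1, t_off),
      error = function(e) e)
    if (inherits(res, "error")) {
      failed <- TRUE
      failure <- conditionMessage(res)
      break
    }
    executed <- c(executed, cl)
    b <- as.data.frame(res$beats)
    b <- cbind(cl_ms = cl, beat = seq_len(nrow(b)), b)
    beats[[length(beats) + 1]] <- b
    if (store_traces)
      traces[[as.character(cl)]] <- data.frame(t = res$trace_t,
                                               vm = res$trace_vm)
    state <- res$state
    t_off <- t_off + cl * schedule$beats_per_cl
    if (early_stop) {
      apds <- b$apd90
      ok <- all(b$capture == 1) && all(is.finite(apds))
      if (ok && length(apds) >= 11) {
        a <- anm(tail(apds, 11))
        if (classify_alternans(a, anm_threshold)) {
          early_stopped <- TRUE
          break
        }
      }
    }
  }

  structure(list(
    code = code,
    beats = do.call(rbind, beats),
    cycle_lengths = executed,
    beats_per_cl = schedule$beats_per_cl,
    final_state = structure(stats::setNames(state, .state_names),
                            class = "cell_state", time = t_off),
    traces = traces,
    early_stopped = early_stopped,
    anm_threshold = anm_threshold,
    failed = failed, failure = failure),
    class = "protocol_run")
}

#' @export
print.protocol_run <- function(x, ...) {
  cat("<protocol_run>", length(x$cycle_lengths), "cycle lengths,",
      x$beats_per_cl, "beats each",
      if (x$early_stopped) "(early-stopped)" else "",
      if (x$failed) paste0("\n  FAILED: ", x$failure) else "", "\n")
  invisible(x)
}
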