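# Factorial population sweep over conductance scenarios and its aggregate
# statistics.

#' Enumerate the factorial of conductance scenarios
#'
#' Deterministic lexicographic enumeration (a base-3 counter over the fixed
#' channel order, first channel most significant): row 1 is all levels 0.5,
#' the last row all levels 1.5. The full 10-channel, 3-level design has
#' 59,049 scenarios.
#'
#' @param n_channels Number of varied channels.
#' @param levels Ordered level set.
#' @return Numeric matrix with one scenario code per row; column names are
#'   the channel names (for 10 channels) or `ch1..chd` otherwise; row order
#'   matches scenario index `0..(|levels|^d - 1)`.
#' @export
enumerate_scenarios <- function(n_channels = 10, levels = c(0.5, 1.0, 1.5)) {
  if (!length(levels)) stop("level set must be non-empty")
  d <- n_channels
  grid <- as.matrix(rev(expand.grid(rev(lapply(seq_len(d),
                                               function(i) levels)))))
  dimnames(grid) <- list(NULL, if (d == 10) channel_names()
                         else paste0("ch", seq_len(d)))
  grid
}

.summary_row <- function(sm, schedule) {
  cls <- schedule$cycle_lengths
  anms <- rep(NA_real_, length(cls))
  idx <- match(sm$per_cl$cl_ms, cls)
  anms[idx] <- sm$per_cl$anm
  row <- data.frame(scenario_id = sm$scenario_id,
                    aocl_ms = sm$aocl_ms, ao_mean_apd_ms = sm$ao_mean_apd_ms,
                    quality = sm$quality)
  lv <- as.data.frame(as.list(stats::setNames(as.numeric(sm$code),
                                              paste0("level_",
                                                     channel_names()))))
  an <- as.data.frame(as.list(stats::setNames(anms,
                                              paste0("anm_cl", cls))))
  cbind(row[, "scenario_id", drop = FALSE], lv,
        row[, c("aocl_ms", "ao_mean_apd_ms", "quality")], an)
}

#' Run the conductance-scenario sweep
#'
#' Executes the descending pacing protocol and the scenario summary for each
#' requested scenario. Per-scenario numerical failures are recorded as
#' quality-flagged rows and never abort the sweep. The result is independent
#' of worker count and execution order, and a checkpoint file makes the sweep
#' resumable (already-completed scenario ids are skipped).
#'
#' @param scenario_ids Integer scenario indices (0-based) to run.
#' @param base Base `conductance_set`.
#' @param schedule A `pacing_schedule`.
#' @param cfg An `integrator_config`.
#' @param early_stop Halt each run after the first alternans-positive cycle
#'   length (sufficient for AOCL / AO meanAPD; the default).
#' @param workers Number of parallel workers (forked; 1 = serial).
#' @param checkpoint Optional CSV path: completed rows are appended as they
#'   finish and skipped on re-run.
#' @param ... Further arguments passed to [run_protocol()] (e.g.
#'   `ss_max_beats`, `anm_threshold`).
#' @return A sweep table (data frame): `scenario_id`, ten `level_*` columns,
#'   `aocl_ms`, `ao_mean_apd_ms`, `quality`, and wide `anm_cl*` columns (NA
#'   for cycle lengths not executed under early stopping).
#' @export
run_sweep <- function(scenario_ids, base = default_conductances(),
                      schedule = build_schedule(),
                      cfg = integrator_config(), early_stop = TRUE,
                      workers = 1, checkpoint = NULL, ...) {
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint)
    scenario_ids <- setdiff(scenario_ids, done$scenario_id)
  }
  one <- function(id) {
    code <- scenario_code(id)
    g <- apply_scenario(base, code)
    run <- run_protocol(g, schedule, cfg, early_stop = early_stop,
                        code = code, ...)
    .summary_row(summarize_scenario(run), schedule)
  }
  rows <- if (workers > 1) {
    parallel::mclapply(scenario_ids, one, mc.cores = workers)
  } else {
    lapply(scenario_ids, one)
  }
  tab <- do.call(rbind, rows)
  if (!is.null(checkpoint) && !is.null(tab)) {
    utils::write.csv(rbind(done, tab), checkpoint, row.names = FALSE)
  }
  tab <- rbind(done, tab)
  tab <- tab[order(tab$scenario_id), ]
  rownames(tab) <- NULL
  tab
}

#' Write or read a sweep table as CSV
#'
#' @param table A sweep table from [run_sweep()].
#' @param path CSV path.
#' @return `read_sweep_table()` returns the table.
#' @export
write_sweep_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sweep_table
#' @export
read_sweep_table <- function(path) utils::read.csv(path)

#' Population statistics of a sweep table
#'
#' Quality-flagged rows are excluded (their count is reported). Over the
#' remaining rows: the maximal and minimal alternans-positive AOCL with the
#' number of scenarios attaining each, per-AOCL-stratum summaries of the
#' onset meanAPD, the count of non-alternans scenarios (AOCL = 0), and the
#' Pearson correlation between AOCL and AO meanAPD. The correlation over
#' alternans-positive scenarios only is primary; the variant including
#' non-alternans (0, 0) rows is also reported.
#'
#' @param table A sweep table.
#' @return A list of class `sweep_stats`.
#' @export
aggregate_sweep <- function(table) {
  if (!nrow(table)) stop("sweep table is empty")
  excluded <- sum(table$quality %in% c("failed", "no_complete_cls"))
  tab <- table[!table$quality %in% c("failed", "no_complete_cls"), ]
  pos <- tab[tab$aocl_ms > 0, ]
  strata <- NULL
  if (nrow(pos)) {
    sp <- split(pos$ao_mean_apd_ms, pos$aocl_ms)
    strata <- data.frame(aocl_ms = as.numeric(names(sp)),
                         n = vapply(sp, length, 1L),
                         mean_ao = vapply(sp, mean, 1),
                         min_ao = vapply(sp, min, 1),
                         max_ao = vapply(sp, max, 1))
    strata <- strata[order(-strata$aocl_ms), ]
    rownames(strata) <- NULL
  }
  cor_pos <- if (nrow(pos) >= 3 && stats::sd(pos$aocl_ms) > 0 &&
                 stats::sd(pos$ao_mean_apd_ms) > 0)
    stats::cor(pos$aocl_ms, pos$ao_mean_apd_ms) else NA_real_
  cor_all <- if (nrow(tab) >= 3 && stats::sd(tab$aocl_ms) > 0 &&
                 stats::sd(tab$ao_mean_apd_ms) > 0)
    stats::cor(tab$aocl_ms, tab$ao_mean_apd_ms) else NA_real_
  structure(list(
    n = nrow(tab),
    n_excluded = excluded,
    n_non_alternans = sum(tab$aocl_ms == 0),
    n_alternans = nrow(pos),
    max_aocl_ms = if (nrow(pos)) max(pos$aocl_ms) else NA_real_,
    n_at_max_aocl = if (nrow(pos)) sum(pos$aocl_ms == max(pos$aocl_ms))
                    else 0L,
    min_aocl_ms = if (nrow(pos)) min(pos$aocl_ms) else NA_real_,
    n_at_min_aocl = if (nrow(pos)) sum(pos$aocl_ms == min(pos$aocl_ms))
                    else 0L,
    strata = strata,
    cor_aocl_ao = cor_pos,
    cor_aocl_ao_incl_zero = cor_all),
    class = "sweep_stats")
}

#' @export
print.sweep_stats <- function(x, ...) {
  cat("<sweep_stats>", x$n, "scenarios (", x$n_excluded, "excluded ),",
      x$n_non_alternans, "non-alternans\n")
  cat("  AOCL max", x$max_aocl_ms, "ms (n =", x$n_at_max_aocl, "), min",
      x$min_aocl_ms, "ms (n =", x$n_at_min_aocl, ")\n")
  cat("  cor(AOCL, AO meanAPD) =", round(x$cor_aocl_ao, 3),
      "( incl. zeros:", round(x$cor_aocl_ao_incl_zero, 3), ")\n")
  invisible(x)
}
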