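#!/usr/bin/env Rscript
# Thin command-line wrapper around run_sweep() for running (slices of) the
# 59,049-scenario factorial on a cluster. The checkpoint file doubles as the
# output and makes interrupted runs resumable.
#
# Usage:
#   Rscript scripts/sweep.R --indices 0:999 --out table.csv \
#       [--workers N] [--no-early-stop]

suppressPackageStartupMessages(library(alternanspop))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
idx <- arg_val("--indices", "0:59048")
rng <- as.integer(strsplit(idx, ":", fixed = TRUE)[[1]])
ids <- seq(rng[1], rng[2])
out <- arg_val("--out", "sweep_table.csv")
workers <- as.integer(arg_val("--workers", "1"))
early <- !("--no-early-stop" %in% args)

tab <- run_sweep(ids, workers = workers, early_stop = early,
                 checkpoint = out)
write_sweep_table(tab, out)
message("wrote ", nrow(tab), " scenario rows to ", out)
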