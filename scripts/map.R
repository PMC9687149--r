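#!/usr/bin/env Rscript
# Builds the dimensionally stacked population map from a sweep table and
# optimizes its axis ordering.
#
# Usage:
#   Rscript scripts/map.R --in table.csv --value aocl_ms \
#       [--method heuristic|exhaustive] [--seed S] [--out grid.csv]

suppressPackageStartupMessages(library(alternanspop))

args <- commandArgs(trailingOnly = TRUE)
arg_val <- function(flag, default) {
  i <- match(flag, args)
  if (is.na(i) || i == length(args)) default else args[i + 1]
}
tab <- read_sweep_table(arg_val("--in", "sweep_table.csv"))
value <- arg_val("--value", "aocl_ms")
method <- arg_val("--method", "heuristic")
seed <- as.integer(arg_val("--seed", "1"))
out <- arg_val("--out", "grid.csv")

fit <- optimize_axis_order(tab, value, method = method, seed = seed)
grid <- build_grid(tab, fit$order, value)
write_grid(grid, out)
message("axis order: ", paste(fit$order$channels, collapse = " > "),
        " (objective ", fit$objective, ")")
message("wrote ", out, " and ", out, ".axes.txt")
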