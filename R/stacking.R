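# Dimensional stacking: embed the factorial scenario grid into a 2-D pixel
# map and optimize the axis ordering by the neighbor-difference objective.

#' Axis ordering for dimensional stacking
#'
#' Channels are listed from most to least influential and assigned
#' alternately to the x- and y-axis nesting positions, outermost (largest
#' stride) first: rank 1 is the outermost x channel, rank 2 the outermost y
#' channel, and so on.
#'
#' @param channels Character vector: a permutation of the stacked channel
#'   names, most influential first.
#' @param levels Ordered level set shared by all channels.
#' @return A list of class `axis_order` with `channels`, `x_group`,
#'   `y_group` (outermost first) and `levels`.
#' @export
axis_order <- function(channels, levels = c(0.5, 1.0, 1.5)) {
  d <- length(channels)
  if (anyDuplicated(channels)) stop("channels must be a permutation")
  structure(list(channels = channels,
                 x_group = channels[seq(1, d, by = 2)],
                 y_group = if (d > 1) channels[seq(2, d, by = 2)]
                           else character(0),
                 levels = levels),
            class = "axis_order")
}

.axis_coord <- function(codes, group, channels_in_code, levels) {
  # codes: matrix (rows = scenarios) with columns named by channel
  n <- length(group)
  if (!n) return(rep(0L, nrow(codes)))
  strides <- length(levels)^((n - 1):0)
  coord <- rep(0, nrow(codes))
  for (i in seq_len(n)) {
    digit <- match(codes[, group[i]], levels) - 1
    if (any(is.na(digit))) stop("off-grid level for channel ", group[i])
    coord <- coord + digit * strides[i]
  }
  as.integer(coord)
}

#' Pixel coordinates of scenarios under an axis ordering
#'
#' Mixed-radix encoding: within each axis group the outermost channel has the
#' largest stride (81, 27, 9, 3, 1 for five 3-level channels); level 0.5 maps
#' to digit 0, 1.0 to 1, 1.5 to 2. Over a full factorial the mapping is a
#' bijection onto the grid.
#'
#' @param code One scenario code (vector) or a matrix of codes (one per row)
#'   with columns in channel order.
#' @param order An `axis_order`.
#' @return Data frame with 0-based integer columns `x`, `y`.
#' @export
stack_coordinates <- function(code, order) {
  if (is.null(dim(code))) code <- matrix(code, nrow = 1)
  if (is.null(colnames(code))) {
    if (ncol(code) == 10) colnames(code) <- channel_names()
    else colnames(code) <- paste0("ch", seq_len(ncol(code)))
  }
  data.frame(
    x = .axis_coord(code, order$x_group, colnames(code), order$levels),
    y = .axis_coord(code, order$y_group, colnames(code), order$levels))
}

.level_matrix <- function(table, channels) {
  cols <- paste0("level_", channels)
  missing <- setdiff(cols, names(table))
  if (length(missing))
    stop("sweep table lacks level columns: ", paste(missing, collapse = ", "))
  m <- as.matrix(table[, cols])
  colnames(m) <- channels
  m
}

#' Build the stacked population grid
#'
#' Fills the 2-D pixel grid from a full-factorial sweep table under the given
#' axis ordering. Non-alternans scenarios carry the value 0 and are marked by
#' the sentinel attribute (they are real map pixels, rendered gray).
#'
#' @param table Sweep table covering the full factorial of the stacked
#'   channels (level columns `level_<channel>` plus the value column).
#' @param order An `axis_order`.
#' @param value Column holding the scalar to map, e.g. `"aocl_ms"` or
#'   `"ao_mean_apd_ms"`.
#' @return Numeric matrix (rows indexed by y, columns by x) of class
#'   `population_grid`, with attributes `axis_order`, `value` and `sentinel`
#'   (logical matrix marking value-0 non-alternans pixels).
#' @export
build_grid <- function(table, order, value = "aocl_ms") {
  codes <- .level_matrix(table, order$channels)
  d <- length(order$channels)
  nl <- length(order$levels)
  nx <- nl^length(order$x_group)
  ny <- nl^length(order$y_group)
  if (nrow(codes) != nl^d) {
    idx <- apply(codes, 1, function(cd)
      sum((match(cd, order$levels) - 1) * nl^((d - 1):0)))
    stop("table must cover the full factorial (", nl^d, " scenarios); ",
         "missing indices: ",
         paste(utils::head(setdiff(0:(nl^d - 1), idx), 20), collapse = ", "))
  }
  xy <- stack_coordinates(codes, order)
  if (anyDuplicated(xy$x + nx * xy$y) > 0)
    stop("duplicate scenarios in table")
  grid <- matrix(NA_real_, nrow = ny, ncol = nx)
  grid[cbind(xy$y + 1, xy$x + 1)] <- table[[value]]
  sentinel <- matrix(FALSE, nrow = ny, ncol = nx)
  sentinel[cbind(xy$y + 1, xy$x + 1)] <- table[[value]] == 0
  structure(grid, class = c("population_grid", "matrix", "array"),
            axis_order = order, value = value, sentinel = sentinel)
}

#' Neighbor-difference objective of a population grid
#'
#' The sum over all pixels of the absolute differences to the left, right,
#' up and down neighbors; terms for neighbors outside the grid are omitted
#' (no wraparound). Each adjacent pair therefore contributes twice. The
#' objective is 0 iff the grid is constant and is invariant under
#' transposition.
#'
#' @param grid A numeric matrix (e.g. from [build_grid()]).
#' @return Scalar objective value.
#' @export
map_objective <- function(grid) {
  g <- unclass(grid)
  nr <- nrow(g); nc <- ncol(g)
  v <- if (nr > 1) sum(abs(g[-1, , drop = FALSE] -
                           g[-nr, , drop = FALSE])) else 0
  h <- if (nc > 1) sum(abs(g[, -1, drop = FALSE] -
                           g[, -nc, drop = FALSE])) else 0
  2 * (v + h)
}

# all permutations of x (small n), one per row
.permutations <- function(x) {
  n <- length(x)
  if (n == 1) return(matrix(x, 1, 1))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- .permutations(x[-i])
    out[[i]] <- cbind(x[i], rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

.order_objective <- function(channels, table, value, levels) {
  map_objective(build_grid(table, axis_order(channels, levels), value))
}

#' Optimize the axis ordering of a population map
#'
#' Finds the channel ordering whose dimensionally stacked map minimizes the
#' neighbor-difference objective. Swapping the x- and y-axis groups leaves
#' the objective unchanged, so orderings are enumerated modulo that symmetry
#' (`d!/2` candidates). `method = "exhaustive"` returns the global minimizer
#' (deterministic tie-break: lexicographically smallest ordering) and is
#' refused above 7 channels unless `force = TRUE`; `method = "heuristic"`
#' seeds with a main-effect sensitivity ranking and refines by simulated
#' annealing over pairwise swaps with a configured seed.
#'
#' @param table Full-factorial sweep table.
#' @param value Value column to map.
#' @param method `"exhaustive"` or `"heuristic"`.
#' @param channels Channels to stack (defaults to all `level_*` columns of
#'   the table, in channel order).
#' @param levels Ordered level set.
#' @param seed RNG seed for the annealing refinement.
#' @param n_iter Annealing iterations.
#' @param force Allow exhaustive search above 7 channels.
#' @return A list of class `axis_order_fit`: `order` (an `axis_order`),
#'   `objective`, and `method`.
#' @export
optimize_axis_order <- function(table, value = "aocl_ms",
                                method = c("heuristic", "exhaustive"),
                                channels = NULL, levels = c(0.5, 1.0, 1.5),
                                seed = 1L, n_iter = 400L, force = FALSE) {
  method <- match.arg(method)
  if (is.null(channels)) {
    channels <- sub("^level_", "", grep("^level_", names(table),
                                        value = TRUE))
    if (all(channels %in% channel_names()))
      channels <- intersect(channel_names(), channels)
  }
  d <- length(channels)
  obj <- function(ord) .order_objective(ord, table, value, levels)

  if (method == "exhaustive") {
    if (d > 7 && !force)
      stop("exhaustive search over ", d, " channels needs ",
           format(factorial(d) / 2, big.mark = ","),
           " grid evaluations; pass force = TRUE to run it anyway")
    perms <- .permutations(seq_len(d))
    # the x/y swap symmetry halves the search space only when the two axis
    # groups have equal size (even d)
    if (d %% 2 == 0)
      perms <- perms[perms[, 1] < perms[, 2], , drop = FALSE]
    vals <- apply(perms, 1, function(p) obj(channels[p]))
    best <- which(vals == min(vals))
    # lexicographically smallest order among ties
    if (length(best) > 1) {
      key <- apply(perms[best, , drop = FALSE], 1, paste, collapse = ",")
      best <- best[order(key)][1]
    }
    fit <- list(order = axis_order(channels[perms[best[1], ]], levels),
                objective = vals[best[1]], method = "exhaustive")
    return(structure(fit, class = "axis_order_fit"))
  }

  # heuristic: greedy main-effect seeding + simulated annealing over swaps
  codes <- .level_matrix(table, channels)
  vals <- table[[value]]
  effect <- vapply(channels, function(ch) {
    mu <- tapply(vals, codes[, ch], mean)
    max(mu) - min(mu)
  }, 1)
  cur <- channels[order(-effect)]
  cur_obj <- obj(cur)
  best <- cur; best_obj <- cur_obj
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         .GlobalEnv))
  set.seed(seed)
  temp0 <- max(cur_obj, 1) * 0.05
  for (it in seq_len(n_iter)) {
    temp <- temp0 * (1 - (it - 1) / n_iter) + 1e-9
    swap <- sample.int(d, 2)
    cand <- cur
    cand[swap] <- cand[rev(swap)]
    cand_obj <- obj(cand)
    if (cand_obj <= cur_obj ||
        stats::runif(1) < exp((cur_obj - cand_obj) / temp)) {
      cur <- cand; cur_obj <- cand_obj
      if (cur_obj < best_obj) { best <- cur; best_obj <- cur_obj }
    }
  }
  structure(list(order = axis_order(best, levels), objective = best_obj,
                 method = "heuristic"),
            class = "axis_order_fit")
}

#' @export
print.axis_order_fit <- function(x, ...) {
  cat("<axis_order_fit>", x$method, "objective =", x$objective, "\n  order:",
      paste(x$order$channels, collapse = " > "), "\n")
  invisible(x)
}

#' Plot a population grid
#'
#' Renders the stacked map with [graphics::image()]; non-alternans sentinel
#' pixels are drawn gray.
#'
#' @param x A `population_grid`.
#' @param col Color ramp for the scalar values.
#' @param sentinel_col Color for non-alternans pixels.
#' @param ... Passed to [graphics::image()].
#' @return `x`, invisibly.
#' @export
plot.population_grid <- function(x, col = grDevices::hcl.colors(64, "Viridis"),
                                 sentinel_col = "gray70", ...) {
  g <- unclass(x)
  vals <- t(g)  # image() draws x along rows
  graphics::image(seq_len(ncol(g)) - 1, seq_len(nrow(g)) - 1, vals,
                  col = col, xlab = "x pixel", ylab = "y pixel",
                  useRaster = TRUE, ...)
  sent <- attr(x, "sentinel")
  if (any(sent)) {
    idx <- which(t(sent), arr.ind = TRUE)
    graphics::rect(idx[, 1] - 1.5, idx[, 2] - 1.5, idx[, 1] - 0.5,
                   idx[, 2] - 0.5, col = sentinel_col, border = NA)
  }
  invisible(x)
}

#' Export a population grid as CSV plus a sidecar description
#'
#' Writes the grid as a plain CSV matrix and a text sidecar recording the
#' axis ordering, the per-channel strides and the mapped value.
#'
#' @param grid A `population_grid`.
#' @param path CSV path; the sidecar is written to `<path>.axes.txt`.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  utils::write.table(unclass(grid), path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  ord <- attr(grid, "axis_order")
  nl <- length(ord$levels)
  lines <- c(paste("value:", attr(grid, "value")),
             paste("x (outermost first):", paste(ord$x_group,
                                                 collapse = ", ")),
             paste("y (outermost first):", paste(ord$y_group,
                                                 collapse = ", ")),
             paste("x strides:", paste(nl^((length(ord$x_group) - 1):0),
                                       collapse = ", ")),
             paste("y strides:", paste(nl^((length(ord$y_group) - 1):0),
                                       collapse = ", ")))
  writeLines(lines, paste0(path, ".axes.txt"))
  invisible(path)
}
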