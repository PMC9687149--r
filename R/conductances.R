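# Conductance sets, scenario codes and their base-3 indexing.

#' Names of the ten varied maximal conductances
#'
#' Channel order is fixed throughout the package (scenario codes, sweep table
#' level columns and axis orderings all use it): slow and rapid delayed
#' rectifier K+, inward rectifier K+, fast Na+, background Na+, L-type Ca2+,
#' background Ca2+, transient outward K+, plateau Ca2+ and plateau K+.
#'
#' @return Character vector of length 10.
#' @export
channel_names <- function() {
  c("g_Ks", "g_Kr", "g_K1", "g_Na", "g_bNa",
    "g_CaL", "g_bCa", "g_to", "g_pCa", "g_pK")
}

# full parameter vector layout expected by the C++ core
.param_names <- c(
  "g_Ks", "g_Kr", "g_K1", "g_Na", "g_bNa", "g_CaL", "g_bCa", "g_to",
  "g_pCa", "g_pK",
  "p_NaK", "k_NaCa", "V_maxup", "V_leak", "a_rel", "b_rel", "c_rel",
  "Na_o", "Ca_o", "K_o")

#' Default maximal conductances and fixed model parameters
#'
#' Returns the reference conductance set of the epicardial human ventricular
#' myocyte model: the ten varied maximal conductances (nS/pF) at their
#' control (100%) values, plus the non-varied pump/exchanger maxima, SR
#' release parameters and external ion concentrations of the reference model.
#'
#' @return A named numeric vector of class `conductance_set`.
#' @examples
#' g <- default_conductances()
#' g["g_Ks"]   # 0.245 nS/pF
#' @export
default_conductances <- function() {
  g <- c(
    g_Ks  = 0.245,
    g_Kr  = 0.096,
    g_K1  = 5.405,
    g_Na  = 14.838,
    g_bNa = 0.00029,
    g_CaL = 0.0000398,
    g_bCa = 0.000592,
    g_to  = 0.294,
    g_pCa = 0.025,
    g_pK  = 0.0146,
    # non-varied model constants (reference-model values)
    p_NaK   = 1.362,     # Na/K pump maximum, pA/pF
    k_NaCa  = 1000,      # Na/Ca exchanger maximum, pA/pF
    V_maxup = 0.000425,  # SERCA uptake maximum, mM/ms
    V_leak  = 8e-5,      # SR leak rate, 1/ms
    a_rel   = 0.016464,  # CICR release, mM/ms
    b_rel   = 0.25,      # CICR half-saturation, mM
    c_rel   = 0.008232,  # CICR baseline release, mM/ms
    Na_o    = 140,       # mM
    Ca_o    = 2,         # mM
    K_o     = 5.4        # mM
  )
  structure(g, class = "conductance_set")
}

.validate_conductances <- function(g) {
  if (!is.numeric(g) || !all(.param_names %in% names(g)))
    stop("conductance set must contain parameters: ",
         paste(.param_names, collapse = ", "))
  if (any(!is.finite(g[channel_names()])) || any(g[channel_names()] <= 0))
    stop("all 10 varied conductances must be finite and > 0")
  invisible(g)
}

.validate_code <- function(code, levels = c(0.5, 1.0, 1.5)) {
  if (length(code) != 10)
    stop("scenario code must have exactly 10 entries (one per channel)")
  if (!all(code %in% levels))
    stop("scenario code levels must all be in {",
         paste(levels, collapse = ", "), "}")
  invisible(code)
}

#' Scale a conductance set by a scenario code
#'
#' Multiplies each of the ten varied maximal conductances by its scale level
#' (50%, 100% or 150% of control); all non-varied model constants are left
#' unchanged.
#'
#' @param base A `conductance_set` (see [default_conductances()]).
#' @param code Numeric vector of 10 scale levels over \{0.5, 1.0, 1.5\}, in
#'   [channel_names()] order.
#' @return A `conductance_set` with the scaled conductances.
#' @examples
#' g <- apply_scenario(default_conductances(), c(0.5, rep(1, 9)))
#' g["g_Ks"]   # 0.1225
#' @export
apply_scenario <- function(base, code) {
  .validate_conductances(base)
  .validate_code(code)
  out <- base
  out[channel_names()] <- base[channel_names()] * as.numeric(code)
  out
}

#' Convert between scenario codes and integer indices
#'
#' Scenario codes are enumerated as a base-3 counter over the fixed channel
#' order, the first channel being the most significant digit: index 0 is all
#' levels 0.5, index `3^10 - 1 = 59048` is all levels 1.5.
#'
#' @param index Integer scenario index (0-based), in `[0, 3^n_channels - 1]`.
#' @param n_channels Number of varied channels (10 for the full design).
#' @param levels Ordered level set (default 0.5, 1.0, 1.5).
#' @return `scenario_code()` returns the level vector; `scenario_index()` the
#'   integer index.
#' @examples
#' scenario_code(0)                  # all 0.5
#' scenario_index(rep(1.5, 10))      # 59048
#' @export
scenario_code <- function(index, n_channels = 10, levels = c(0.5, 1.0, 1.5)) {
  nl <- length(levels)
  if (any(index < 0) || any(index > nl^n_channels - 1))
    stop("scenario index out of range [0, ", nl^n_channels - 1, "]")
  digits <- integer(n_channels)
  rem <- index
  for (k in n_channels:1) {
    digits[k] <- rem %% nl
    rem <- rem %/% nl
  }
  levels[digits + 1]
}

#' @rdname scenario_code
#' @param code Numeric level vector (length `n_channels`).
#' @export
scenario_index <- function(code, levels = c(0.5, 1.0, 1.5)) {
  digits <- match(code, levels) - 1
  if (any(is.na(digits))) stop("code contains off-grid levels")
  sum(digits * length(levels)^(rev(seq_along(code)) - 1))
}

#' Read or write a conductance set as flat key-value text
#'
#' One `key = value` pair per line, suitable for restartable runs.
#'
#' @param g A `conductance_set`.
#' @param path File path.
#' @return `read_conductances()` returns a `conductance_set`.
#' @export
write_conductances <- function(g, path) {
  .validate_conductances(g)
  writeLines(sprintf("%s = %.17g", names(g), as.numeric(g)), path)
  invisible(path)
}

#' @rdname write_conductances
#' @export
read_conductances <- function(path) {
  kv <- read.table(path, sep = "=", strip.white = TRUE,
                   col.names = c("key", "value"),
                   colClasses = c("character", "numeric"))
  g <- structure(kv$value, names = kv$key, class = "conductance_set")
  .validate_conductances(g)
  g
}
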