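# R surface of the myocyte ODE model: cell state, integrator configuration,
# current computation, single stepping and the quiescent resting state.

.state_names <- c("Vm", "m", "h", "j", "d", "f", "fCa", "r", "s",
                  "xr1", "xr2", "xs", "g", "Ca_i", "Ca_SR", "Na_i", "K_i")
.gate_names <- c("m", "h", "j", "d", "f", "fCa", "r", "s", "xr1", "xr2", "xs",
                 "g")
.conc_names <- c("Ca_i", "Ca_SR", "Na_i", "K_i")

#' Reference initial cell state
#'
#' The published initial conditions of the epicardial reference model:
#' membrane potential at rest, gates at their resting values and nominal
#' intracellular concentrations. Use [resting_state()] for a properly
#' equilibrated quiescent state.
#'
#' @return Named numeric vector of class `cell_state` (17 state variables)
#'   with a `time` attribute in ms.
#' @export
initial_state <- function() {
  s <- c(Vm = -86.2, m = 0, h = 0.75, j = 0.75, d = 0, f = 1, fCa = 1,
         r = 0, s = 1, xr1 = 0, xr2 = 1, xs = 0, g = 1,
         Ca_i = 0.0002, Ca_SR = 0.2, Na_i = 11.6, K_i = 138.3)
  structure(s, class = "cell_state", time = 0)
}

.validate_state <- function(state) {
  if (!is.numeric(state) || length(state) != 17 ||
      !identical(names(state), .state_names))
    stop("cell state must be a named numeric vector with variables: ",
         paste(.state_names, collapse = ", "))
  if (any(!is.finite(state)))
    stop("non-finite cell state variable: ",
         paste(names(state)[!is.finite(state)], collapse = ", "))
  hh <- setdiff(.gate_names, "fCa")
  if (any(state[hh] < 0 | state[hh] > 1))
    stop("gating variables must lie in [0, 1]")
  # the Ca-dependent inactivation steady state marginally exceeds unity at
  # diastolic Ca in the reference formulation
  if (state["fCa"] < 0 || state["fCa"] > 1.05)
    stop("fCa out of range [0, 1.05]")
  if (any(state[.conc_names] <= 0))
    stop("ionic concentrations must be > 0")
  invisible(state)
}

#' Integrator and stimulus configuration
#'
#' @param dt Integration time step, ms.
#' @param cm Membrane capacitance per unit area, uF/cm^2. Currents are
#'   carried per unit capacitance (pA/pF), so `cm` only fixes the unit
#'   convention of the membrane equation.
#' @param stim_amplitude Stimulus current, pA/pF (negative = depolarizing).
#' @param stim_duration Stimulus duration, ms.
#' @return A list of class `integrator_config`.
#' @export
integrator_config <- function(dt = 0.02, cm = 2.0, stim_amplitude = -52,
                              stim_duration = 1) {
  if (dt <= 0) stop("dt must be > 0")
  if (stim_duration < dt) stop("stimulus duration must be >= dt")
  structure(list(dt = dt, cm = cm, stim_amplitude = stim_amplitude,
                 stim_duration = stim_duration),
            class = "integrator_config")
}

.as_params <- function(g) {
  .validate_conductances(g)
  as.numeric(g[.param_names])
}

#' Membrane currents at a given state
#'
#' Evaluates the twelve Hodgkin-Huxley-type membrane currents of the
#' epicardial reference model and their sum `I_ion`.
#'
#' @param state A `cell_state`.
#' @param g A `conductance_set`.
#' @return Named numeric vector of the 12 currents plus `I_ion`, pA/pF.
#' @export
compute_currents <- function(state, g) {
  .validate_state(state)
  tt_currents_cpp(as.numeric(state), .as_params(g))
}

#' Advance the cell state by one or more fixed steps
#'
#' Rush-Larsen exponential updates for the Hodgkin-Huxley gates and forward
#' Euler for membrane potential and concentrations.
#'
#' @param state A `cell_state`.
#' @param g A `conductance_set`.
#' @param cfg An `integrator_config`.
#' @param i_stim Stimulus current applied throughout, pA/pF.
#' @param n Number of steps.
#' @return The advanced `cell_state`; its `time` attribute grows by `n * dt`.
#' @export
step_state <- function(state, g, cfg = integrator_config(), i_stim = 0,
                       n = 1) {
  .validate_state(state)
  out <- tt_integrate_cpp(as.numeric(state), .as_params(g), n * cfg$dt,
                          cfg$dt, i_stim)
  structure(stats::setNames(out, .state_names), class = "cell_state",
            time = attr(state, "time") %||% 0 + n * cfg$dt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Quiescent resting state
#'
#' Integrates the unstimulated model from the reference initial conditions
#' until the membrane potential drifts by less than `tol_mv` over successive
#' `window` ms segments, so that the returned state is a reproducible
#' quiescent equilibrium.
#'
#' @param g A `conductance_set`.
#' @param cfg An `integrator_config`.
#' @param tol_mv Maximum allowed Vm drift per window, mV.
#' @param window Drift-check window, ms.
#' @param horizon Maximum total equilibration time, ms.
#' @return A quiescent `cell_state`.
#' @export
resting_state <- function(g = default_conductances(),
                          cfg = integrator_config(), tol_mv = 0.1,
                          window = 1000, horizon = 60000) {
  p <- .as_params(g)
  s <- as.numeric(initial_state())
  t <- 0
  repeat {
    s2 <- tt_integrate_cpp(s, p, window, cfg$dt, 0)
    t <- t + window
    if (abs(s2[1] - s[1]) < tol_mv) {
      return(structure(stats::setNames(s2, .state_names),
                       class = "cell_state", time = 0))
    }
    if (t >= horizon)
      stop("cell failed to reach a quiescent state within ", horizon, " ms")
    s <- s2
  }
}

#' Read or write a cell state snapshot as flat key-value text
#'
#' @param state A `cell_state`.
#' @param path File path.
#' @return `read_state()` returns a `cell_state`.
#' @export
write_state <- function(state, path) {
  .validate_state(state)
  writeLines(sprintf("%s = %.17g", names(state), as.numeric(state)), path)
  invisible(path)
}

#' @rdname write_state
#' @export
read_state <- function(path) {
  kv <- read.table(path, sep = "=", strip.white = TRUE,
                   col.names = c("key", "value"),
                   colClasses = c("character", "numeric"))
  s <- structure(kv$value, names = kv$key, class = "cell_state", time = 0)
  .validate_state(s)
  s
}
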