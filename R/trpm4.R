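#' TRPM4 channel parameters
#'
#' Calcium-activated non-selective cation (TRPM4) channel with
#' Hodgkin-Huxley-style kinetics: a single activation gate relaxing with time
#' constant `tau_m` toward a Hill function of intracellular calcium, and an
#' ohmic current law. The reversal potential defaults to -40 mV. The Hill
#' midpoint `ca_half` and coefficient `hill_n` are free parameters normally
#' estimated from an activation-curve dataset with [fit_hill()].
#'
#' @param gmax Maximum conductance density, S/cm^2.
#' @param e_rev Reversal potential, mV.
#' @param ca_half Half-activation calcium concentration, mM (> 0).
#' @param hill_n Hill coefficient (> 0).
#' @param tau_m Activation time constant, ms (> 0).
#' @param power Integer exponent on the activation gate (>= 1).
#' @param inactivation Optional [gate_params()] inactivation slot; absent by
#'   default.
#' @return An object of class `trpm4_params`.
#' @export
trpm4_params <- function(gmax = 2e-4, e_rev = -40, ca_half = 1e-3,
                         hill_n = 2, tau_m = 10, power = 1,
                         inactivation = NULL) {
  if (ca_half <= 0) stop("`ca_half` must be positive")
  if (hill_n <= 0) stop("`hill_n` must be positive")
  if (tau_m <= 0) stop("configuration error: `tau_m` must be positive")
  if (power < 1 || power != round(power)) stop("`power` must be an integer >= 1")
  if (gmax < 0) stop("`gmax` must be non-negative")
  if (!is.null(inactivation)) stopifnot(inherits(inactivation, "gate_params"))
  structure(list(gmax = gmax, e_rev = e_rev, ca_half = ca_half,
                 hill_n = hill_n, tau_m = tau_m, power = as.integer(power),
                 inactivation = inactivation),
            class = "trpm4_params")
}

#' TRPM4 steady-state activation (Hill equation)
#'
#' `1 / (1 + (ca_half/cai)^n)`: zero at `cai = 0`, 0.5 at `cai = ca_half`,
#' strictly increasing in `cai`, and a shifted logistic when plotted against
#' `log10(cai)`.
#'
#' @param cai Intracellular calcium, mM (vectorized, >= 0).
#' @param params A [trpm4_params()].
#' @return Dimensionless activation in \[0, 1).
#' @export
hill_inf <- function(cai, params) {
  stopifnot(inherits(params, "trpm4_params"))
  if (any(cai < 0)) stop("`cai` must be non-negative")
  hill_activation(cai, params$ca_half, params$hill_n)
}

#' Advance the TRPM4 activation gate one time step
#'
#' Exponential relaxation toward [hill_inf()] with time constant `tau_m`,
#' exact at frozen calcium.
#'
#' @param m Gate value in \[0, 1\].
#' @param cai Intracellular calcium, mM.
#' @param params A [trpm4_params()].
#' @param dt Time step, ms (> 0).
#' @return Updated gate value.
#' @export
trpm4_gate_step <- function(m, cai, params, dt) {
  stopifnot(inherits(params, "trpm4_params"), m >= 0, m <= 1, dt > 0)
  minf <- hill_inf(cai, params)
  minf + (m - minf) * exp(-dt / params$tau_m)
}

#' TRPM4 current density
#'
#' `gmax * m^power * (v - e_rev)` in uA/cm^2; inward (negative,
#' depolarizing) for `v < e_rev`.
#'
#' @param params A [trpm4_params()].
#' @param m Activation gate value in \[0, 1\].
#' @param v Membrane potential, mV.
#' @param h Optional inactivation gate value (used only if the params carry an
#'   inactivation slot).
#' @return Current density, uA/cm^2.
#' @export
trpm4_current <- function(params, m, v, h = 1) {
  stopifnot(inherits(params, "trpm4_params"), m >= 0, m <= 1)
  f <- m^params$power
  if (!is.null(params$inactivation)) f <- f * h^params$inactivation$power
  params$gmax * f * (v - params$e_rev) * 1e3
}
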