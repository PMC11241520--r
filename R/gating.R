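#' Gate parameters for a Hodgkin-Huxley-type gating variable
#'
#' A gate relaxes with first-order kinetics toward a steady state that is
#' either a Boltzmann function of membrane potential (`kind = "boltzmann"`)
#' or a Hill function of intracellular calcium (`kind = "hill"`, used for the
#' calcium-activated SK/IK conductances). The steady-state Boltzmann form is
#' `1 / (1 + exp((v + v_half)/slope))`: a negative `slope` gives a sigmoid
#' increasing with depolarization (activation), a positive `slope` a
#' decreasing one (inactivation). The sign is always explicit in the
#' configuration; the code never flips it silently.
#'
#' @param kind `"boltzmann"` (voltage-dependent) or `"hill"`
#'   (calcium-dependent).
#' @param v_half Half-activation parameter in mV; the sigmoid midpoint sits at
#'   `v = -v_half`. Boltzmann gates only.
#' @param slope Signed slope factor in mV; must be non-zero. Boltzmann gates
#'   only.
#' @param tau Time constant in ms. Either a single positive number or a
#'   two-column `data.frame`/list with components `v` (mV, strictly
#'   increasing) and `tau` (ms) defining a piecewise-linear voltage table
#'   (flat extrapolation outside the table).
#' @param power Small non-negative integer exponent on the gate in the current
#'   law.
#' @param ca_half Half-activation calcium concentration in mM. Hill gates
#'   only.
#' @param hill_n Hill coefficient (dimensionless, > 0). Hill gates only.
#' @return An object of class `gate_params`.
#' @export
gate_params <- function(kind = c("boltzmann", "hill"), v_half = NULL,
                        slope = NULL, tau = 1, power = 1,
                        ca_half = NULL, hill_n = NULL) {
  kind <- match.arg(kind)
  if (kind == "boltzmann") {
    if (is.null(v_half) || is.null(slope)) {
      stop("boltzmann gate needs `v_half` and `slope`")
    }
    if (!is.finite(slope) || slope == 0) stop("`slope` must be non-zero")
  } else {
    if (is.null(ca_half) || is.null(hill_n)) {
      stop("hill gate needs `ca_half` and `hill_n`")
    }
    if (ca_half <= 0) stop("`ca_half` must be positive")
    if (hill_n <= 0) stop("`hill_n` must be positive")
  }
  if (power < 0 || power != round(power)) {
    stop("`power` must be a non-negative integer")
  }
  tau <- validate_tau(tau)
  structure(list(kind = kind, v_half = v_half, slope = slope, tau = tau,
                 power = as.integer(power), ca_half = ca_half,
                 hill_n = hill_n),
            class = "gate_params")
}

validate_tau <- function(tau) {
  if (is.numeric(tau) && length(tau) == 1L) {
    if (!is.finite(tau) || tau <= 0) stop("configuration error: tau must be > 0")
    return(tau)
  }
  if (is.list(tau) && all(c("v", "tau") %in% names(tau))) {
    v <- as.numeric(tau$v); tv <- as.numeric(tau$tau)
    if (length(v) != length(tv) || length(v) < 2L) {
      stop("tau table needs matching `v` and `tau` vectors of length >= 2")
    }
    if (any(diff(v) <= 0)) stop("tau table `v` must be strictly increasing")
    if (any(!is.finite(tv)) || any(tv <= 0)) {
      stop("configuration error: tau must be > 0 everywhere")
    }
    return(list(v = v, tau = tv))
  }
  stop("`tau` must be a positive scalar or a list(v=, tau=) table")
}

tau_at <- function(gate, v) {
  tau <- gate$tau
  if (is.numeric(tau)) return(tau)
  stats::approx(tau$v, tau$tau, xout = v, rule = 2)$y
}

#' Boltzmann steady-state value
#'
#' `1 / (1 + exp((v + v_half)/slope))`, bounded in (0, 1) and strictly
#' monotone in `v` with direction set by the sign of `slope`.
#'
#' @param v Membrane potential, mV (vectorized).
#' @param gate A boltzmann [gate_params()].
#' @return Dimensionless steady-state value(s) in (0, 1).
#' @export
boltzmann_inf <- function(v, gate) {
  stopifnot(inherits(gate, "gate_params"), gate$kind == "boltzmann")
  1 / (1 + exp((v + gate$v_half) / gate$slope))
}

#' Gate steady state at given voltage and calcium
#'
#' Dispatches on the gate kind: Boltzmann in voltage or Hill in calcium.
#'
#' @inheritParams boltzmann_inf
#' @param cai Intracellular calcium, mM (used by hill gates).
#' @return Steady-state value(s) in \[0, 1\].
#' @export
gate_inf <- function(v, gate, cai = NULL) {
  if (gate$kind == "boltzmann") return(boltzmann_inf(v, gate))
  if (is.null(cai)) stop("hill gate needs `cai`")
  hill_activation(cai, gate$ca_half, gate$hill_n)
}

# shared Hill form, increasing in cai, 0 at cai = 0
hill_activation <- function(cai, ca_half, n) {
  ifelse(cai <= 0, 0, 1 / (1 + (ca_half / cai)^n))
}

#' Advance a gating variable one time step
#'
#' Exponential-integrator closed form of the first-order relaxation
#' `dm/dt = (m_inf - m)/tau` at frozen voltage/calcium:
#' `m' = m_inf + (m - m_inf) * exp(-dt/tau)`. Exact for constant
#' (v, cai) over the step, unconditionally stable, and keeps `m` in \[0, 1\].
#'
#' @param m Current gate value in \[0, 1\].
#' @param v Membrane potential, mV.
#' @param gate A [gate_params()].
#' @param dt Time step, ms (> 0).
#' @param cai Intracellular calcium, mM (hill gates).
#' @return Updated gate value.
#' @export
gate_step <- function(m, v, gate, dt, cai = NULL) {
  stopifnot(dt > 0, m >= 0, m <= 1)
  minf <- gate_inf(v, gate, cai)
  tau <- tau_at(gate, v)
  minf + (m - minf) * exp(-dt / tau)
}

#' Hodgkin-Huxley channel specification
#'
#' @param name Channel identifier (unique within a model).
#' @param gmax Maximum conductance density, S/cm^2 (>= 0).
#' @param e_rev Reversal (Nernst) potential, mV.
#' @param activation,inactivation Optional [gate_params()]. A channel with
#'   neither gate is a pure ohmic leak.
#' @param carries_ca Logical; does this channel's current feed the
#'   intracellular calcium pool?
#' @return An object of class `hh_channel`.
#' @export
hh_channel <- function(name, gmax, e_rev, activation = NULL,
                       inactivation = NULL, carries_ca = FALSE) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("`name` must be a non-empty string")
  }
  if (!is.numeric(gmax) || length(gmax) != 1L || !is.finite(gmax) || gmax < 0) {
    stop("`gmax` must be a single non-negative number")
  }
  if (!is.null(activation)) stopifnot(inherits(activation, "gate_params"))
  if (!is.null(inactivation)) stopifnot(inherits(inactivation, "gate_params"))
  structure(list(name = name, gmax = gmax, e_rev = e_rev,
                 activation = activation, inactivation = inactivation,
                 carries_ca = isTRUE(carries_ca)),
            class = "hh_channel")
}

#' Ohmic Hodgkin-Huxley current density
#'
#' `gmax * m^x * h^y * (v - e_rev)` in uA/cm^2, outward positive. Gates whose
#' slot is absent contribute a factor of 1.
#'
#' @param spec An [hh_channel()].
#' @param m,h Gate values in \[0, 1\] (`h` ignored if the channel has no
#'   inactivation gate).
#' @param v Membrane potential, mV.
#' @return Current density, uA/cm^2.
#' @export
hh_current <- function(spec, m = 1, h = 1, v) {
  stopifnot(inherits(spec, "hh_channel"))
  f <- 1
  if (!is.null(spec$activation)) f <- f * m^spec$activation$power
  if (!is.null(spec$inactivation)) f <- f * h^spec$inactivation$power
  # S/cm^2 * mV = mA/cm^2; *1e3 -> uA/cm^2
  spec$gmax * f * (v - spec$e_rev) * 1e3
}
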