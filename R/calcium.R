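#' Intracellular calcium pool parameters
#'
#' Minimal single-pool submembrane calcium balance feeding the
#' calcium-activated conductances (BK, SK, IK, TRPM4): calcium current influx
#' into an effective shell of the given depth, and first-order extrusion back
#' toward the resting level:
#' `d(cai)/dt = -i_ca / (2 F depth) - (cai - ca_rest) / tau_removal`.
#' With `clamp = TRUE` the pool is held at `ca_rest` (the strict
#' "maintained at 150 nM" reading, useful for resting-potential experiments).
#' The shell depth and removal time constant are effective parameters, not
#' measured quantities.
#'
#' @param ca_rest Resting (extrusion target) calcium, mM.
#' @param tau_removal Extrusion time constant, ms.
#' @param depth_um Effective submembrane shell depth, micrometres.
#' @param clamp Logical; hold calcium fixed at `ca_rest`.
#' @return An object of class `ca_pool_params`.
#' @export
ca_pool_params <- function(ca_rest = 150e-6, tau_removal = 10,
                           depth_um = 1, clamp = FALSE) {
  if (ca_rest <= 0 || tau_removal <= 0 || depth_um <= 0) {
    stop("configuration error: calcium pool parameters must be positive")
  }
  structure(list(ca_rest = ca_rest, tau_removal = tau_removal,
                 depth_um = depth_um, clamp = isTRUE(clamp)),
            class = "ca_pool_params")
}

FARADAY <- 96485.33212  # C/mol

#' Advance the calcium pool one time step
#'
#' Exponential update of the linear pool ODE at frozen calcium influx:
#' the equilibrium at constant influx is
#' `ca_inf = ca_rest - tau_removal * i_ca / (2 F depth)` and
#' `cai' = ca_inf + (cai - ca_inf) * exp(-dt/tau_removal)`. An inward
#' (negative) calcium current raises `cai`. The result is floored at 1e-9 mM.
#'
#' @param cai Current calcium, mM (> 0).
#' @param i_ca_total Total calcium current density, uA/cm^2 (inward negative).
#' @param params A [ca_pool_params()].
#' @param dt Time step, ms (> 0).
#' @return Updated calcium, mM.
#' @export
ca_step <- function(cai, i_ca_total, params, dt) {
  stopifnot(inherits(params, "ca_pool_params"), cai > 0, dt > 0)
  if (params$clamp) return(params$ca_rest)
  # uA/cm^2 -> mM/ms: 1e-3 / (2 F depth_cm)
  influx <- -i_ca_total * 1e-3 / (2 * FARADAY * params$depth_um * 1e-4)
  ca_inf <- params$ca_rest + params$tau_removal * influx
  out <- ca_inf + (cai - ca_inf) * exp(-dt / params$tau_removal)
  if (out < 1e-9) {
    warning("calcium pool floored at 1e-9 mM")
    out <- 1e-9
  }
  out
}
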