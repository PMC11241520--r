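#' Total membrane current balance (dV/dt)
#'
#' Evaluates the right-hand side of the membrane equation at a given state:
#' `C dV/dt = -(sum of ionic current densities) + injected current density`,
#' returning dV/dt in mV/ms. All nine HH-type conductances, BK, TRPM4 and the
#' leak contribute; the pulse stimulus enters as current, the alpha synapse
#' as a conductance times driving force.
#'
#' @param model A `cell_model`.
#' @param state A `cell_state` (see [initial_state()]).
#' @param t Time, ms (for stimulus evaluation).
#' @param stimulus A stimulus object or `NULL`.
#' @return dV/dt in mV/ms, with attribute `"currents"` holding the named
#'   per-channel current densities (uA/cm^2).
#' @export
total_membrane_current <- function(model, state, t = 0, stimulus = NULL) {
  stopifnot(inherits(model, "cell_model"), inherits(state, "cell_state"))
  v <- state$v
  nm <- names(model$channels)
  i_chan <- vapply(seq_along(nm), function(j) {
    hh_current(model$channels[[j]], m = state$gates[1, j],
               h = state$gates[2, j], v = v)
  }, numeric(1))
  names(i_chan) <- nm
  i_trp <- trpm4_current(model$trpm4, m = state$gates[1, "trpm4"], v = v,
                         h = state$gates[2, "trpm4"])
  i_bk <- bk_current(model$bk, state$bk, v)
  area <- lateral_area(model$geometry)
  i_stim_d <- 0
  if (!is.null(stimulus)) {
    if (inherits(stimulus, "pulse_stimulus")) {
      i_stim_d <- pulse_current(t, stimulus) * 1e-3 / area  # nA -> uA/cm^2
    } else {
      i_stim_d <- -synaptic_current(t, stimulus, v) * 1e-3 / area
    }
  }
  currents <- c(i_chan, trpm4 = i_trp, bk = i_bk)
  dvdt <- (-sum(currents) + i_stim_d) / model$passive$c_specific_uF_cm2
  attr(dvdt, "currents") <- currents
  dvdt
}

#' Advance the whole-cell state one time step
#'
#' Single operator-split implicit step (see [simulate_cell()] for the
#' scheme). Deterministic: identical inputs give bit-identical outputs.
#'
#' @param model A `cell_model`.
#' @param state A `cell_state`.
#' @param stimulus A stimulus object or `NULL`.
#' @param dt Time step, ms (> 0).
#' @return The updated `cell_state`.
#' @export
step_cell <- function(model, state, stimulus = NULL, dt = 0.04) {
  res <- simulate_cell(model, stimulus = stimulus, t_stop = dt, dt = dt,
                       state = state)
  attr(res, "final_state")
}

#' Simulate the whole-cell model
#'
#' Integrates the membrane equation from `t = 0` (or from the time carried by
#' a supplied state) to `t_stop` with the fixed-step operator-split scheme:
#' at each step the calcium pool, all HH gates and the BK occupancy advance
#' at frozen voltage (exact exponential / matrix-exponential updates), then
#' the voltage advances by backward Euler on the ohmic current sum. The
#' default `dt` of 0.04 ms matches the whole-cell simulations the model
#' reproduces. The initial transient of an unequilibrated run settles within
#' the first few hundred ms; callers typically discard a 500-ms window.
#'
#' @param model A `cell_model`.
#' @param stimulus A [pulse_stimulus()], [alpha_synapse()] or `NULL`.
#' @param t_stop Simulation end time, ms (> 0).
#' @param dt Time step, ms.
#' @param v_init Initial potential, mV (ignored if `state` given).
#' @param equilibrate Pre-equilibrate the initial state (see
#'   [initial_state()]).
#' @param state Optional `cell_state` to continue from.
#' @param record_every Record every k-th step (thinning; integration always
#'   runs at `dt`).
#' @return A `dsm_trace`: a `data.frame` with columns `t` (ms), `v` (mV),
#'   `cai` (mM), one current-density column per channel (uA/cm^2; `i_` prefix,
#'   BK included), `bk_open` (conducting open probability) and `i_stim` (nA).
#'   Attributes: `dt`, `stimulus`, `final_state`.
#' @examples
#' \donttest{
#' model <- default_dsm_model()
#' tr <- simulate_cell(model, pulse_stimulus(0.6), t_stop = 800)
#' extract_features(tr)
#' }
#' @export
simulate_cell <- function(model, stimulus = NULL, t_stop = 2000, dt = 0.04,
                          v_init = -52, equilibrate = FALSE, state = NULL,
                          record_every = 1L) {
  stopifnot(inherits(model, "cell_model"), t_stop > 0, dt > 0)
  if (is.null(state)) {
    state <- initial_state(model, v0 = v_init, equilibrate = equilibrate)
  }
  stopifnot(inherits(state, "cell_state"))
  n_steps <- as.integer(round(t_stop / dt))
  if (abs(n_steps * dt - t_stop) > 1e-9 * max(1, t_stop)) {
    n_steps <- ceiling(t_stop / dt)
  }
  pk <- pack_model(model)
  res <- dsm_run_core(pk$chan, pk$tau_tables, pk$bk, pk$ca,
                      pk$c_specific, pk$area, pack_stimulus(stimulus),
                      state$v, state$cai, state$gates, state$bk,
                      state$t, dt, n_steps, as.integer(record_every))
  nm <- rownames(pk$chan)
  imat <- res$i
  colnames(imat) <- paste0("i_", c(nm, "bk"))
  out <- data.frame(t = res$t, v = res$v, cai = res$cai, imat,
                    bk_open = res$bk_open, i_stim = res$i_stim)
  fs <- res$state
  gates <- fs$gates
  colnames(gates) <- c(names(model$channels), "trpm4")
  rownames(gates) <- c("m", "h")
  final_state <- structure(list(v = fs$v, cai = fs$cai, gates = gates,
                                bk = stats::setNames(fs$bk, bk_state_names),
                                t = fs$t),
                           class = "cell_state")
  structure(out, dt = dt * record_every, step_dt = dt, stimulus = stimulus,
            final_state = final_state,
            class = c("dsm_trace", "data.frame"))
}

#' @export
print.dsm_trace <- function(x, ...) {
  stim <- attr(x, "stimulus")
  cat(sprintf("<dsm_trace> %d samples, t = %.6g .. %.6g ms (dt = %g ms)\n",
              nrow(x), x$t[1], x$t[nrow(x)], attr(x, "dt")))
  if (is.null(stim)) {
    cat("  stimulus: none\n")
  } else if (inherits(stim, "pulse_stimulus")) {
    cat(sprintf("  stimulus: pulse %g units x %g ms at %g ms\n",
                stim$amplitude, stim$duration, stim$onset))
  } else {
    cat(sprintf("  stimulus: alpha synapse %g uS (tau %g ms) at %g ms\n",
                stim$g_peak, stim$tau_alpha, stim$onset))
  }
  cat(sprintf("  v range: [%.2f, %.2f] mV\n", min(x$v), max(x$v)))
  invisible(x)
}

#' Stimulus onset of a trace
#'
#' @param trace A `dsm_trace`.
#' @return Onset time in ms, or `Inf` when the trace is unstimulated.
#' @export
stimulus_onset <- function(trace) {
  stim <- attr(trace, "stimulus")
  if (is.null(stim)) Inf else stim$onset
}
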