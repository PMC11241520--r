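#' Square current pulse stimulus
#'
#' Injected current of constant amplitude over a closed-left interval
#' `[onset, onset + duration)`. Amplitude is a raw number in the declared
#' stimulus unit (default nA): published threshold amplitudes are compared on
#' the raw number regardless of the unit label, and `unit_nA` converts one
#' stimulus unit to nA for the physics.
#'
#' @param amplitude Pulse amplitude in stimulus units.
#' @param onset Pulse onset, ms.
#' @param duration Pulse duration, ms (> 0).
#' @param unit_nA Size of one stimulus unit in nA (default 1).
#' @return An object of class `pulse_stimulus` (also `stimulus`).
#' @export
pulse_stimulus <- function(amplitude, onset = 500, duration = 10,
                           unit_nA = 1) {
  if (duration <= 0) stop("`duration` must be positive")
  if (onset < 0) stop("`onset` must be non-negative")
  structure(list(kind = "pulse", amplitude = amplitude, onset = onset,
                 duration = duration, unit_nA = unit_nA),
            class = c("pulse_stimulus", "stimulus"))
}

#' Alpha-function synaptic stimulus
#'
#' Synaptic conductance transient
#' `g(t) = g_peak * ((t - onset)/tau_alpha) * exp(1 - (t - onset)/tau_alpha)`
#' for `t >= onset`, peaking at exactly `g_peak` one `tau_alpha` after onset,
#' driving the current `g(t) * (v - e_syn)`.
#'
#' @param g_peak Peak conductance, uS (>= 0).
#' @param tau_alpha Alpha-function time constant, ms (> 0).
#' @param e_syn Synaptic reversal potential, mV.
#' @param onset Stimulus onset, ms.
#' @return An object of class `alpha_synapse` (also `stimulus`).
#' @export
alpha_synapse <- function(g_peak, tau_alpha = 5, e_syn = 0, onset = 500) {
  if (g_peak < 0) stop("`g_peak` must be non-negative")
  if (tau_alpha <= 0) stop("`tau_alpha` must be positive")
  if (onset < 0) stop("`onset` must be non-negative")
  structure(list(kind = "alpha", g_peak = g_peak, tau_alpha = tau_alpha,
                 e_syn = e_syn, onset = onset),
            class = c("alpha_synapse", "stimulus"))
}

#' Calibrated stimulus protocols of the shipped model
#'
#' The study protocols used with [default_dsm_model()]: a 10-ms square
#' current pulse in stimulus units of 0.1 nA (the calibrated model's rheobase
#' is raw amplitude 0.56, i.e. 56 pA), and an alpha-function synaptic
#' conductance with the calibrated time constant and a 0 mV reversal (the
#' calibrated threshold peak conductance is 0.0079 uS). Both default to a
#' 500 ms onset, leaving the standard settling window before the stimulus.
#'
#' @param amplitude Pulse amplitude in 0.1 nA stimulus units.
#' @param onset Stimulus onset, ms.
#' @return A stimulus object.
#' @export
default_pulse_protocol <- function(amplitude = 0.56, onset = 500) {
  pulse_stimulus(amplitude, onset = onset, duration = 10, unit_nA = 0.1)
}

#' @rdname default_pulse_protocol
#' @param g_peak Peak synaptic conductance, uS.
#' @export
default_syn_protocol <- function(g_peak = 0.0079, onset = 500) {
  alpha_synapse(g_peak, tau_alpha = 0.4124, e_syn = 0, onset = onset)
}

#' Pulse current at time t
#'
#' @param t Time, ms (vectorized, >= 0).
#' @param p A [pulse_stimulus()].
#' @return Injected current in nA.
#' @export
pulse_current <- function(t, p) {
  stopifnot(inherits(p, "pulse_stimulus"))
  ifelse(t >= p$onset & t < p$onset + p$duration,
         p$amplitude * p$unit_nA, 0)
}

#' Alpha-function conductance at time t
#'
#' @param t Time, ms (vectorized, >= 0).
#' @param s An [alpha_synapse()].
#' @return Conductance in uS.
#' @export
alpha_conductance <- function(t, s) {
  stopifnot(inherits(s, "alpha_synapse"))
  x <- (t - s$onset) / s$tau_alpha
  ifelse(x <= 0, 0, s$g_peak * x * exp(1 - x))
}

#' Synaptic current at time t and voltage v
#'
#' @param t Time, ms.
#' @param s An [alpha_synapse()].
#' @param v Membrane potential, mV.
#' @return Current in nA (uS * mV = nA), outward positive.
#' @export
synaptic_current <- function(t, s, v) {
  alpha_conductance(t, s) * (v - s$e_syn)
}
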