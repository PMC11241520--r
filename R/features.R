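#' Extract action-potential features from a voltage trace
#'
#' Operational definitions used throughout the package:
#' \describe{
#'   \item{rmp}{Mean voltage over the last 100 ms before the stimulus onset
#'     (for an unstimulated trace, the last 100 ms of the trace).}
#'   \item{spike_detected}{A local voltage maximum after onset exceeding
#'     `rmp + spike_rise` (default +30 mV) whose rising phase reaches
#'     `dvdt_crit`. The criterion default of 1.9 mV/ms is a calibrated
#'     property of the shipped model: its just-suprathreshold action
#'     potentials leave the saddle-point creep at about that rate-of-rise, so
#'     this value reads the AP threshold at the foot of the regenerative
#'     upstroke.}
#'   \item{threshold_v}{Voltage at the onset of the final regenerative
#'     excursion: the last upward crossing of the dV/dt criterion before the
#'     spike peak. (Strong stimuli -- the synaptic kick, or pulses well above
#'     rheobase -- drive dV/dt above the criterion at stimulus onset, so a
#'     first-crossing rule would measure the stimulus artifact; the last
#'     crossing isolates the intrinsic threshold.)}
#'   \item{ap_duration}{Time from the threshold crossing until the voltage
#'     first falls back below `threshold_v` after the peak (threshold-level
#'     duration, not half-height).}
#'   \item{ahp_depth}{`rmp - min(v)` after the peak (positive when the
#'     after-hyperpolarization undershoots rest).}
#'   \item{nonphysiological}{TRUE when the post-spike voltage fails to return
#'     to within 10 mV of the pre-stimulus RMP within 500 ms of the peak
#'     (given a long enough trace), or when a secondary regenerative spike
#'     occurs after the stimulus has ended.}
#' }
#'
#' @param trace A `dsm_trace` (or data.frame with `t` and `v`).
#' @param onset Stimulus onset, ms; defaults to the onset carried by the
#'   trace.
#' @param settle Settling window, ms; the trace must be longer than this.
#' @param dvdt_crit Threshold-detection dV/dt criterion, mV/ms.
#' @param spike_rise Minimum peak height above RMP for spike detection, mV.
#' @param return_window Time allowed for return to rest, ms.
#' @return An object of class `ap_features`: list with `rmp`, `threshold_v`,
#'   `peak_v`, `peak_t`, `ap_duration`, `ahp_depth`, `spike_detected`,
#'   `nonphysiological`.
#' @export
extract_features <- function(trace, onset = NULL, settle = 500,
                             dvdt_crit = 1.9, spike_rise = 30,
                             return_window = 500) {
  t <- trace$t
  v <- trace$v
  if (length(t) < 3L) stop("trace too short")
  if ((t[length(t)] - t[1]) <= settle) {
    stop("trace shorter than the settling window")
  }
  if (is.null(onset)) {
    onset <- if (inherits(trace, "dsm_trace")) stimulus_onset(trace) else Inf
  }
  dt <- t[2] - t[1]

  end_pre <- if (is.finite(onset)) onset else t[length(t)]
  pre <- t >= (end_pre - 100) & t <= end_pre
  if (!any(pre)) stop("no pre-stimulus window available for RMP")
  rmp <- mean(v[pre])

  out <- list(rmp = rmp, threshold_v = NA_real_, peak_v = NA_real_,
              peak_t = NA_real_, ap_duration = NA_real_,
              ahp_depth = NA_real_, spike_detected = FALSE,
              nonphysiological = FALSE)
  class(out) <- "ap_features"
  if (!is.finite(onset)) return(out)

  io <- which(t >= onset)[1]
  if (is.na(io) || io >= length(t) - 1L) return(out)
  dvdt <- c(diff(v) / diff(t), 0)  # left-aligned slope

  # candidate spike peaks: local maxima above rmp + spike_rise whose rise
  # reached the dv/dt criterion
  idx <- seq(io, length(t) - 1L)
  vm <- v[idx]
  loc <- which(diff(sign(diff(vm))) < 0) + 1L
  peaks <- idx[loc][vm[loc] >= rmp + spike_rise]
  peaks <- peaks[vapply(peaks, function(p) {
    any(dvdt[io:max(io, p - 1L)] >= dvdt_crit)
  }, logical(1))]
  if (length(peaks) == 0L) return(out)

  pk <- peaks[1]
  out$spike_detected <- TRUE
  out$peak_v <- v[pk]
  out$peak_t <- t[pk]

  # threshold: last upward crossing of the dv/dt criterion before the peak
  seg <- dvdt[io:(pk - 1L)]
  below <- which(seg < dvdt_crit)
  thr_idx <- if (length(below) == 0L) io else {
    cross <- below[below < length(seg)]
    cross <- cross[seg[cross + 1L] >= dvdt_crit]
    if (length(cross) == 0L) io else io + max(cross)  # sample where crossing lands
  }
  out$threshold_v <- v[thr_idx]

  # duration at threshold level
  after <- which(v[(pk + 1L):length(v)] < out$threshold_v)
  if (length(after) > 0L) {
    out$ap_duration <- t[pk + after[1]] - t[thr_idx]
  }

  post <- v[(pk + 1L):length(v)]
  out$ahp_depth <- rmp - min(post)

  # return-to-rest check
  ret <- which(post <= rmp + 10)
  horizon <- t[length(t)] - t[pk]
  if (length(ret) == 0L || t[pk + ret[1]] - t[pk] > return_window) {
    if (horizon >= return_window) out$nonphysiological <- TRUE
  }
  if (is.na(out$ap_duration) && horizon >= return_window) {
    out$nonphysiological <- TRUE
  }
  # secondary regenerative depolarization after the stimulus is over
  stim <- attr(trace, "stimulus")
  stim_end <- if (is.null(stim)) onset else {
    if (inherits(stim, "pulse_stimulus")) stim$onset + stim$duration
    else stim$onset + 8 * stim$tau_alpha
  }
  late <- peaks[t[peaks] > max(stim_end, t[pk])]
  if (length(late) > 0L) out$nonphysiological <- TRUE
  out
}

#' @export
print.ap_features <- function(x, ...) {
  cat("<ap_features>\n")
  cat(sprintf("  rmp          %8.2f mV\n", x$rmp))
  if (x$spike_detected) {
    cat(sprintf("  threshold_v  %8.2f mV\n", x$threshold_v))
    cat(sprintf("  peak_v       %8.2f mV (at %.2f ms)\n", x$peak_v, x$peak_t))
    cat(sprintf("  ap_duration  %8.2f ms\n", x$ap_duration))
    cat(sprintf("  ahp_depth    %8.2f mV\n", x$ahp_depth))
    cat(sprintf("  nonphysiological: %s\n", x$nonphysiological))
  } else {
    cat("  no spike detected\n")
  }
  invisible(x)
}

#' Minimal spiking stimulus amplitude (rheobase search)
#'
#' Grid bisection on the stimulus amplitude: given a non-spiking `lo` and a
#' spiking `hi`, returns the smallest amplitude on the `resolution` grid that
#' elicits a spike. The amplitude is the pulse current (stimulus units) for
#' `kind = "pulse"` or the alpha-synapse peak conductance (uS) for
#' `kind = "alpha"`.
#'
#' @param model A `cell_model`.
#' @param kind `"pulse"` or `"alpha"`.
#' @param lo,hi Bracket amplitudes (lo must not spike; hi must spike).
#' @param resolution Grid resolution of the returned amplitude.
#' @param onset Stimulus onset, ms.
#' @param duration Pulse duration, ms (pulse only).
#' @param unit_nA Size of one pulse stimulus unit in nA (pulse only; the
#'   returned threshold is the raw amplitude in these units).
#' @param tau_alpha,e_syn Alpha-synapse parameters (alpha only).
#' @param t_stop,dt Simulation settings per probe run.
#' @param state Optional pre-equilibrated initial state (reused across
#'   probes; computed once from the model if absent).
#' @param ... Passed to [extract_features()].
#' @return Amplitude on the resolution grid, with attributes `features`
#'   (features of the spiking run at the returned amplitude) and `n_runs`.
#' @export
threshold_search <- function(model, kind = c("pulse", "alpha"), lo, hi,
                             resolution, onset = 500, duration = 10,
                             unit_nA = 1, tau_alpha = 5, e_syn = 0,
                             t_stop = onset + 500, dt = 0.04, state = NULL,
                             ...) {
  kind <- match.arg(kind)
  stopifnot(lo < hi, resolution > 0)
  if (is.null(state)) state <- initial_state(model)
  make_stim <- function(amp) {
    if (kind == "pulse") {
      pulse_stimulus(amp, onset = onset, duration = duration,
                     unit_nA = unit_nA)
    } else {
      alpha_synapse(amp, tau_alpha = tau_alpha, e_syn = e_syn, onset = onset)
    }
  }
  probe <- function(amp) {
    tr <- simulate_cell(model, make_stim(amp), t_stop = t_stop, dt = dt,
                        state = state)
    extract_features(tr, ...)
  }
  n_runs <- 2L
  f_lo <- probe(lo)
  f_hi <- probe(hi)
  if (f_lo$spike_detected) stop("bracket error: `lo` already elicits a spike")
  if (!f_hi$spike_detected) stop("bracket error: `hi` does not elicit a spike")
  k_lo <- floor(lo / resolution + 1e-9)
  k_hi <- ceiling(hi / resolution - 1e-9)
  f_best <- f_hi
  while (k_hi - k_lo > 1L) {
    k_mid <- (k_lo + k_hi) %/% 2L
    f <- probe(k_mid * resolution)
    n_runs <- n_runs + 1L
    if (f$spike_detected) {
      k_hi <- k_mid
      f_best <- f
    } else {
      k_lo <- k_mid
    }
  }
  structure(k_hi * resolution, features = f_best, n_runs = n_runs)
}

#' Conductance sensitivity sweep
#'
#' Rescales one channel's maximum conductance over a grid of factors, reruns
#' the stimulated model, extracts AP features, and normalizes every feature
#' to its value at factor 1.0 (which must be in the grid).
#'
#' @param model A `cell_model`.
#' @param channel Channel name (HH channel, `"bk"` or `"trpm4"`).
#' @param factors Numeric grid of scale factors including 1.0.
#' @param stimulus Stimulus applied in every run.
#' @param t_stop,dt Simulation settings.
#' @param ... Passed to [extract_features()].
#' @return An object of class `sweep_result`: data.frame with the factor
#'   grid, raw features (`rmp`, `threshold_v`, `peak_v`, `ap_duration`,
#'   `ahp_depth`), flags (`spike`, `nonphysiological`, `failed`), and
#'   normalized columns (`*_norm`, relative to factor 1.0).
#' @export
conductance_sweep <- function(model, channel, factors, stimulus,
                              t_stop = 1200, dt = 0.04, ...) {
  stopifnot(any(abs(factors - 1) < 1e-12))
  rows <- lapply(factors, function(f) {
    m <- scale_channel(model, channel, f)
    feats <- tryCatch({
      tr <- simulate_cell(m, stimulus, t_stop = t_stop, dt = dt)
      extract_features(tr, ...)
    }, error = function(e) e)
    if (inherits(feats, "error")) {
      data.frame(factor = f, rmp = NA_real_, threshold_v = NA_real_,
                 peak_v = NA_real_, ap_duration = NA_real_,
                 ahp_depth = NA_real_, spike = FALSE,
                 nonphysiological = NA, failed = TRUE,
                 message = conditionMessage(feats))
    } else {
      data.frame(factor = f, rmp = feats$rmp, threshold_v = feats$threshold_v,
                 peak_v = feats$peak_v, ap_duration = feats$ap_duration,
                 ahp_depth = feats$ahp_depth, spike = feats$spike_detected,
                 nonphysiological = feats$nonphysiological, failed = FALSE,
                 message = "")
    }
  })
  out <- do.call(rbind, rows)
  ref <- out[abs(out$factor - 1) < 1e-12, , drop = FALSE][1, ]
  for (col in c("rmp", "threshold_v", "peak_v", "ap_duration", "ahp_depth")) {
    out[[paste0(col, "_norm")]] <- out[[col]] / ref[[col]]
  }
  structure(out, channel = channel, class = c("sweep_result", "data.frame"))
}

#' Channel knockout / compensation experiment
#'
#' Silences one channel (gmax = 0) and runs the stimulated model twice: once
#' with no further changes and once with a compensation set of absolute
#' maximum conductances applied to other channels. The experiment is
#' "reproduced" when the muted-only run is spikeless and the compensated run
#' spikes under the same stimulus.
#'
#' @param model A `cell_model`.
#' @param mute Channel name to silence.
#' @param compensate Named numeric vector/list of absolute gmax values
#'   (S/cm^2) for other channels, or `NULL` for the muted-only pair member.
#' @param stimulus Stimulus applied to both runs.
#' @param t_stop,dt Simulation settings.
#' @param ... Passed to [extract_features()].
#' @return List with `muted` and `compensated` (each: `trace`, `features`),
#'   and `reproduced` (logical; `NA` for the compensated half if no
#'   compensation set was given).
#' @export
knockout_experiment <- function(model, mute, compensate = NULL, stimulus,
                                t_stop = 1200, dt = 0.04, ...) {
  if (!mute %in% channel_names(model)) {
    stop(sprintf("unknown channel '%s'", mute))
  }
  muted <- set_channel_gmax(model, mute, 0)
  tr_m <- simulate_cell(muted, stimulus, t_stop = t_stop, dt = dt)
  f_m <- extract_features(tr_m, ...)
  out <- list(muted = list(trace = tr_m, features = f_m),
              compensated = NULL, reproduced = NA)
  if (!is.null(compensate)) {
    comp <- muted
    for (nm in names(compensate)) {
      if (nm == mute) stop("compensation must not touch the muted channel")
      comp <- set_channel_gmax(comp, nm, as.numeric(compensate[[nm]]))
    }
    tr_c <- simulate_cell(comp, stimulus, t_stop = t_stop, dt = dt)
    f_c <- extract_features(tr_c, ...)
    out$compensated <- list(trace = tr_c, features = f_c)
    out$reproduced <- !f_m$spike_detected && f_c$spike_detected
  }
  out
}

#' Shipped compensation set for the T-type knockout experiment
#'
#' Absolute maximum conductances (S/cm^2) for TRPM4, the L-type channel and
#' the inward rectifier that restore spiking under the baseline
#' just-suprathreshold pulse after the T-type conductance is silenced. Found
#' with the package's calibration workflow; only these three channels are
#' touched.
#'
#' @return Named numeric vector.
#' @export
default_cat_compensation <- function() {
  m <- default_dsm_model()
  c(trpm4 = unname(channel_gmax(m, "trpm4")) * 1.6,
    cal = unname(channel_gmax(m, "cal")) * 2.0,
    kir = unname(channel_gmax(m, "kir")) * 0.3)
}
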