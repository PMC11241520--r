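#' Degrees-of-freedom corrected RMSE (standard error of the regression)
#'
#' `S = sqrt( sum((y_exp - y_sim)^2) / (M - N) )` where M is the number of
#' data points and N the number of fitted parameters. S is zero iff the two
#' series are identical, and invariant under a common permutation of both.
#'
#' @param y_exp,y_sim Numeric series of equal length M.
#' @param n_params Number of fitted parameters N (M > N required).
#' @return The S statistic, in the units of the observable.
#' @export
rmse_s <- function(y_exp, y_sim, n_params = 0) {
  if (length(y_exp) != length(y_sim)) stop("series must have equal length")
  m <- length(y_exp)
  if (m <= n_params) {
    stop("degrees-of-freedom error: need more data points than parameters")
  }
  sqrt(sum((y_exp - y_sim)^2) / (m - n_params))
}

#' Goodness-of-fit verdict
#'
#' A fit is satisfactory when S is strictly below a stated fraction (default
#' 5%) of the experimental data range (max - min).
#'
#' @param S The statistic from [rmse_s()].
#' @param data_range Range (max - min) of the experimental values (> 0).
#' @param fraction Threshold fraction of the range.
#' @return List with `passed` (logical, strict inequality) and `threshold`.
#' @export
gof_pass <- function(S, data_range, fraction = 0.05) {
  if (!is.finite(data_range) || data_range <= 0) {
    stop("degenerate data range")
  }
  threshold <- fraction * data_range
  list(passed = S < threshold, threshold = threshold)
}

#' Synthetic TRPM4 activation-curve dataset
#'
#' Generates (calcium, normalized activation) points emulating a
#' steady-state activation curve measured over a log-calcium axis: calcium
#' sampled uniformly in log10 space, activation from the Hill equation at
#' the stated parameters, plus additive Gaussian noise. Stands in for
#' digitized experimental activation data.
#'
#' @param n Number of points (>= 3).
#' @param ca_half True Hill midpoint, mM.
#' @param hill_n True Hill coefficient.
#' @param noise_sd Additive noise SD on the activation axis.
#' @param log10_range Range of log10(calcium/mM) sampled.
#' @param seed Integer seed (deterministic output).
#' @return data.frame with `cai` (mM) and `activation` (clipped to [0, 1]),
#'   with the generating parameters attached as attributes.
#' @export
simulate_activation_curve <- function(n = 25, ca_half = 1e-3, hill_n = 2,
                                      noise_sd = 0.02,
                                      log10_range = c(-5, -1), seed = 1L) {
  stopifnot(n >= 3, ca_half > 0, hill_n > 0, noise_sd >= 0)
  set.seed(seed)
  lca <- sort(stats::runif(n, log10_range[1], log10_range[2]))
  cai <- 10^lca
  act <- hill_activation(cai, ca_half, hill_n) +
    stats::rnorm(n, 0, noise_sd)
  act <- pmin(pmax(act, 0), 1)
  structure(data.frame(cai = cai, activation = act),
            ca_half = ca_half, hill_n = hill_n, noise_sd = noise_sd,
            seed = seed)
}

#' Fit Hill parameters to an activation dataset
#'
#' Bounded least squares of the Hill equation
#' `1/(1 + (ca_half/cai)^n)` against (calcium, activation) points, using a
#' fixed multi-start grid over log10(ca_half) and n followed by L-BFGS-B
#' refinement -- fully deterministic. The fit report carries the S statistic
#' ([rmse_s()] with N = 2) and the 5%-of-range verdict ([gof_pass()]).
#'
#' @param data data.frame with columns `cai` (mM, > 0) and `activation`
#'   (in [0, 1]); at least 3 points.
#' @param ca_half_bounds,hill_n_bounds Search bounds.
#' @return List of class `hill_fit`: `ca_half`, `hill_n`, `fitted`
#'   (predicted activations), `report` (list: `S`, `threshold`, `passed`,
#'   `n_params`).
#' @export
fit_hill <- function(data, ca_half_bounds = c(1e-6, 1),
                     hill_n_bounds = c(0.3, 8)) {
  if (!all(c("cai", "activation") %in% names(data))) {
    stop("`data` needs columns `cai` and `activation`")
  }
  if (nrow(data) < 3L) stop("need at least 3 data points")
  if (any(data$cai <= 0)) stop("`cai` must be strictly positive")
  cai <- data$cai
  y <- data$activation
  sse <- function(par) {
    pred <- hill_activation(cai, 10^par[1], par[2])
    sum((y - pred)^2)
  }
  lb <- c(log10(ca_half_bounds[1]), hill_n_bounds[1])
  ub <- c(log10(ca_half_bounds[2]), hill_n_bounds[2])
  starts <- expand.grid(
    lch = seq(lb[1] + 0.25, ub[1] - 0.25, length.out = 6),
    n = seq(max(0.5, lb[2]), min(4, ub[2]), length.out = 4))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::optim(c(starts$lch[i], starts$n[i]), sse, method = "L-BFGS-B",
                   lower = lb, upper = ub),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    stop("fit error: Hill fit failed to converge from every start")
  }
  ca_half <- 10^best$par[1]
  hill_n <- best$par[2]
  fitted <- hill_activation(cai, ca_half, hill_n)
  S <- rmse_s(y, fitted, n_params = 2)
  rng <- diff(range(y))
  gp <- if (rng > 0) gof_pass(S, rng) else list(passed = NA, threshold = NA_real_)
  structure(list(ca_half = ca_half, hill_n = hill_n, fitted = fitted,
                 report = list(S = S, threshold = gp$threshold,
                               passed = gp$passed, n_params = 2)),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> ca_half = %.4g mM, n = %.3f | S = %.4g (%s)\n",
              x$ca_half, x$hill_n, x$report$S,
              if (isTRUE(x$report$passed)) "pass" else "fail"))
  invisible(x)
}

#' Calibrate maximum conductances against whole-cell targets
#'
#' Deterministic bounded coordinate descent over the selected channels'
#' maximum conductances, minimizing the weighted squared relative error of
#' measured whole-cell quantities against their targets. Supported targets:
#' \describe{
#'   \item{rmp}{Settled resting potential, mV (unstimulated run).}
#'   \item{pulse_threshold}{10-ms pulse rheobase, stimulus units.}
#'   \item{syn_threshold}{Alpha-synapse peak-conductance threshold, uS.}
#'   \item{threshold_v}{Pulse-derived AP threshold voltage, mV.}
#' }
#' Parameters never leave `(1 - bound, 1 + bound)` times their starting
#' value. When the targets cannot be reached within bounds the best-found
#' model is returned with `converged = FALSE` (no error).
#'
#' @param model Starting `cell_model`.
#' @param targets Named list of target values (subset of the above).
#' @param channels Channels whose gmax may move.
#' @param bound Relative bound on each gmax (default 0.3).
#' @param weights Optional named weights (default 1 for each target).
#' @param grid_points Candidate points per channel per pass.
#' @param passes Number of coordinate-descent passes.
#' @param tol Relative tolerance on each target for declaring convergence.
#' @param measure_opts List of options forwarded to the measurement runs
#'   (`pulse_lo/hi`, `syn_lo/hi`, resolutions, `t_stop`).
#' @return List of class `calibration`: `model`, `report` (data.frame of
#'   target/before/after), `converged`.
#' @export
calibrate_cell <- function(model, targets,
                           channels = c("katp", "kdr", "kv1", "kir", "cat",
                                        "cal", "trpm4"),
                           bound = 0.3, weights = NULL, grid_points = 5,
                           passes = 2, tol = 0.01,
                           measure_opts = list()) {
  stopifnot(inherits(model, "cell_model"), length(targets) > 0)
  known <- c("rmp", "pulse_threshold", "syn_threshold", "threshold_v")
  if (!all(names(targets) %in% known)) {
    stop("targets must be a named subset of: ", paste(known, collapse = ", "))
  }
  if (is.null(weights)) weights <- stats::setNames(rep(1, length(targets)),
                                                   names(targets))
  g0 <- vapply(channels, function(ch) channel_gmax(model, ch), numeric(1))

  objective <- function(m) {
    meas <- measure_targets(m, names(targets), measure_opts)
    err <- vapply(names(targets), function(nm) {
      tv <- targets[[nm]]
      mv <- meas[[nm]]
      if (!is.finite(mv)) return(10)  # measurement failed (e.g. no bracket)
      ((mv - tv) / max(abs(tv), 1e-12))^2 * weights[[nm]]
    }, numeric(1))
    list(value = sum(err), measured = meas)
  }

  cur <- objective(model)
  before <- cur$measured
  for (pass in seq_len(passes)) {
    for (ch in channels) {
      if (cur$value == 0) break
      g_now <- channel_gmax(model, ch)
      cand <- seq(g0[[ch]] * (1 - bound), g0[[ch]] * (1 + bound),
                  length.out = grid_points)
      cand <- unique(c(g_now, cand))
      vals <- lapply(cand, function(g) {
        objective(set_channel_gmax(model, ch, g))
      })
      k <- which.min(vapply(vals, `[[`, numeric(1), "value"))
      if (vals[[k]]$value < cur$value) {
        model <- set_channel_gmax(model, ch, cand[k])
        cur <- vals[[k]]
      }
    }
  }
  after <- cur$measured
  rel_err <- vapply(names(targets), function(nm) {
    abs(after[[nm]] - targets[[nm]]) / max(abs(targets[[nm]]), 1e-12)
  }, numeric(1))
  report <- data.frame(target = names(targets),
                       goal = unlist(targets),
                       before = unlist(before[names(targets)]),
                       after = unlist(after[names(targets)]),
                       rel_error = rel_err)
  structure(list(model = model, report = report,
                 converged = all(rel_err <= tol)),
            class = "calibration")
}

# measure the calibration observables on a model
measure_targets <- function(model, which_targets, opts = list()) {
  o <- utils::modifyList(list(
    pulse_lo = 0.2, pulse_hi = 1.4, pulse_res = 0.01, unit_nA = 0.1,
    syn_lo = 0.002, syn_hi = 0.02, syn_res = 1e-4, tau_alpha = 0.4124,
    onset = 500, t_stop = 1000, dt = 0.04), opts)
  out <- list()
  state <- initial_state(model)
  if ("rmp" %in% which_targets) {
    tr <- simulate_cell(model, NULL, t_stop = o$t_stop, dt = o$dt,
                        state = state)
    out$rmp <- mean(tr$v[tr$t >= o$t_stop - 100])
  }
  need_pulse <- any(c("pulse_threshold", "threshold_v") %in% which_targets)
  if (need_pulse) {
    thr <- tryCatch(
      threshold_search(model, "pulse", lo = o$pulse_lo, hi = o$pulse_hi,
                       resolution = o$pulse_res, onset = o$onset,
                       unit_nA = o$unit_nA, t_stop = o$t_stop, dt = o$dt,
                       state = state),
      error = function(e) NA_real_)
    out$pulse_threshold <- as.numeric(thr)
    out$threshold_v <- if (is.na(thr[1])) NA_real_ else
      attr(thr, "features")$threshold_v
  }
  if ("syn_threshold" %in% which_targets) {
    thr <- tryCatch(
      threshold_search(model, "alpha", lo = o$syn_lo, hi = o$syn_hi,
                       resolution = o$syn_res, onset = o$onset,
                       tau_alpha = o$tau_alpha, t_stop = o$t_stop, dt = o$dt,
                       state = state),
      error = function(e) NA_real_)
    out$syn_threshold <- as.numeric(thr)
  }
  out
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> converged: %s\n", x$converged))
  print(x$report, row.names = FALSE)
  invisible(x)
}
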