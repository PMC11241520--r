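#' BK channel parameters (10-state Markov model)
#'
#' The large-conductance calcium-activated K+ (BK) channel is described by a
#' ten-state continuous-time Markov chain: five closed states C0..C4 and five
#' open states O0..O4 arranged as two horizontal calcium-binding ladders
#' connected by vertical voltage-dependent closed/open transitions. The
#' horizontal rates carry the printed `cai` factors (including on the
#' unbinding side); the vertical rates are multiplied by the voltage factors
#' `a = exp(v/a_efold)` (forward, C->O) and `b = exp(-v/b_efold)` (backward,
#' O->C). `K_O4C4` additionally carries a `cai` factor. The functional form
#' of `a` and `b` is a modelling choice of this package (exponential voltage
#' dependence with configurable e-fold slopes); the base rate constants are
#' fixed model constants.
#'
#' @param gmax Maximum conductance density, S/cm^2.
#' @param e_k Potassium reversal potential, mV.
#' @param k_on,k_coff,k_ooff Calcium binding/unbinding base rate constants.
#' @param co_rates Five forward C->O base rates (C0O0..C4O4).
#' @param oc_rates Five backward O->C base rates (O0C0..O4C4).
#' @param a_efold,b_efold e-fold slopes (mV) of the voltage factors.
#' @param conducting Logical vector of length 5: which of O0..O4 conduct.
#'   The default excludes O0 (conducting open probability = O1+O2+O3+O4); set
#'   `c(FALSE, FALSE, FALSE, FALSE, TRUE)` for the O4-only reading.
#' @param ca_unbinding `"printed"` keeps the published rate table verbatim,
#'   where the calcium unbinding rates and `K_O4C4` carry a `cai` factor.
#'   Because `cai` then cancels from every binding/unbinding ratio and
#'   survives only in the closing rate `K_O4C4`, the steady-state open
#'   probability of that form *decreases* with calcium. `"canonical"` drops
#'   those `cai` factors (the standard form of this 10-state BK lineage),
#'   restoring monotone calcium activation; the shipped whole-cell model
#'   uses it so BK can play its repolarizing role.
#' @return An object of class `bk_params`.
#' @export
bk_params <- function(gmax = 8e-4, e_k = -75,
                      k_on = 335, k_coff = 26, k_ooff = 26,
                      co_rates = c(0.03162, 0.000969, 0.0000381,
                                   0.000881, 0.054324),
                      oc_rates = c(328.1084, 154.1736, 33.6594,
                                   0.097312, 0.000406),
                      a_efold = 25, b_efold = 25,
                      conducting = c(FALSE, TRUE, TRUE, TRUE, TRUE),
                      ca_unbinding = c("printed", "canonical")) {
  ca_unbinding <- match.arg(ca_unbinding)
  stopifnot(length(co_rates) == 5L, length(oc_rates) == 5L,
            length(conducting) == 5L)
  vals <- c(gmax, k_on, k_coff, k_ooff, co_rates, oc_rates)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("all BK rate constants and gmax must be non-negative")
  }
  if (a_efold <= 0 || b_efold <= 0) stop("e-fold slopes must be positive")
  structure(list(gmax = gmax, e_k = e_k, k_on = k_on, k_coff = k_coff,
                 k_ooff = k_ooff, co_rates = co_rates, oc_rates = oc_rates,
                 a_efold = a_efold, b_efold = b_efold,
                 conducting = as.logical(conducting),
                 ca_unbinding = ca_unbinding),
            class = "bk_params")
}

bk_state_names <- c("C0", "C1", "C2", "C3", "C4", "O0", "O1", "O2", "O3", "O4")

# printed ladder multiplicities, first-to-last rung
bk_ladder_up <- c(3, 4, 3, 1)
bk_ladder_down <- c(1, 3, 4, 3)  # rung i+1 -> i for i = 1..4 (C1C0, C2C1, C3C2, C4C3)

#' Build the BK generator matrix
#'
#' Returns the 10x10 infinitesimal generator Q (1/ms) at fixed membrane
#' potential and calcium: `Q[i, j]` is the transition rate from state i to
#' state j (state order C0..C4, O0..O4) and each diagonal entry is minus the
#' row sum of the off-diagonals, so rows sum to zero and probability is
#' conserved. Occupancy evolves as `dP/dt = t(Q) %*% P`.
#'
#' @param params A [bk_params()].
#' @param v Membrane potential, mV.
#' @param cai Intracellular calcium, mM (>= 0).
#' @return 10x10 generator matrix with dimnames C0..O4.
#' @export
bk_rate_matrix <- function(params, v, cai) {
  stopifnot(inherits(params, "bk_params"))
  if (!is.finite(cai) || cai < 0) stop("`cai` must be non-negative")
  a <- exp(v / params$a_efold)
  b <- exp(-v / params$b_efold)
  # "printed": unbinding rates and K_O4C4 carry the published cai factor
  caf <- if (identical(params$ca_unbinding, "canonical")) 1 else cai
  Q <- matrix(0, 10, 10, dimnames = list(bk_state_names, bk_state_names))
  up_on <- bk_ladder_up * params$k_on * cai
  for (i in 1:4) {
    Q[i, i + 1] <- up_on[i]                                    # C(i-1) -> C(i)
    Q[i + 5, i + 6] <- up_on[i]                                # O(i-1) -> O(i)
    Q[i + 1, i] <- bk_ladder_down[i] * params$k_coff * caf     # C(i) -> C(i-1)
    Q[i + 6, i + 5] <- bk_ladder_down[i] * params$k_ooff * caf # O(i) -> O(i-1)
  }
  for (i in 1:5) {
    Q[i, i + 5] <- params$co_rates[i] * a
    back <- params$oc_rates[i] * b
    if (i == 5) back <- back * caf  # K_O4C4 cai factor in the printed form
    Q[i + 5, i] <- back
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Advance BK occupancy one time step
#'
#' Exact propagation of the linear occupancy ODE at frozen (v, cai):
#' `P' = expm(t(Q) * dt) %*% P`. The matrix exponential of a generator is a
#' stochastic matrix, so occupancy remains a probability vector for any dt.
#'
#' @param state Occupancy vector of length 10 (C0..C4, O0..O4), summing to 1.
#' @param params A [bk_params()].
#' @param v Membrane potential, mV.
#' @param cai Intracellular calcium, mM.
#' @param dt Time step, ms (> 0).
#' @return Updated occupancy vector.
#' @export
bk_step <- function(state, params, v, cai, dt) {
  state <- validate_bk_state(state)
  stopifnot(dt > 0)
  Q <- bk_rate_matrix(params, v, cai)
  p <- bk_expm_step(Q, state, dt)  # compiled scaling-and-squaring Pade
  stats::setNames(pmax(p, 0) / sum(pmax(p, 0)), bk_state_names)
}

validate_bk_state <- function(state) {
  state <- as.numeric(state)
  if (length(state) != 10L || any(!is.finite(state)) || any(state < -1e-12)) {
    stop("BK occupancy must be 10 non-negative probabilities")
  }
  if (abs(sum(state) - 1) > 1e-6) {
    stop("BK occupancy must sum to 1")
  }
  state
}

#' BK steady-state occupancy
#'
#' Null-space solution of the generator at fixed (v, cai), normalized to sum
#' to one. At `cai = 0` the ladder rates vanish and the chain splits into five
#' disconnected C/O pairs with no unique stationary distribution.
#'
#' @inheritParams bk_step
#' @return Occupancy vector of length 10.
#' @export
bk_steady_state <- function(params, v, cai) {
  if (!is.finite(cai) || cai <= 0) {
    stop("`cai` must be > 0: at cai = 0 the chain has multiple communicating classes")
  }
  Q <- bk_rate_matrix(params, v, cai)
  # solve t(Q) p = 0 with sum(p) = 1 by replacing one balance row
  A <- t(Q)
  A[10, ] <- 1
  rhs <- c(rep(0, 9), 1)
  p <- solve(A, rhs)
  stats::setNames(pmax(p, 0) / sum(pmax(p, 0)), bk_state_names)
}

#' BK current density
#'
#' `gmax * O * (v - e_k)` where O sums the conducting open states
#' (O1..O4 by default; O0 excluded).
#'
#' @param params A [bk_params()].
#' @param state Occupancy vector of length 10.
#' @param v Membrane potential, mV.
#' @return Current density, uA/cm^2 (outward positive).
#' @export
bk_current <- function(params, state, v) {
  state <- validate_bk_state(state)
  o <- sum(state[6:10][params$conducting])
  params$gmax * o * (v - params$e_k) * 1e3
}

#' Conducting open probability
#'
#' @inheritParams bk_current
#' @return Sum of the conducting open-state occupancies.
#' @export
bk_open_probability <- function(params, state) {
  state <- validate_bk_state(state)
  sum(state[6:10][params$conducting])
}
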