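---
title: "A single-compartment detrusor smooth muscle cell model with TRPM4"
author: "dsmcell"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A single-compartment detrusor smooth muscle cell model with TRPM4}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`dsmcell` simulates an isolated detrusor smooth muscle (DSM) cell as a single
electrical compartment: a cylinder of 200 µm × 6 µm whose lateral membrane
(3.77×10⁻⁵ cm², end caps excluded by the usual single-compartment convention)
carries a specific capacitance of 1 µF/cm², giving C ≈ 37.7 pF, a specific
membrane resistivity of 138 kΩ·cm², and eleven parallel membrane currents.
Cytoplasmic resistivity (183 Ω·cm) is stored for configuration fidelity but
carries no current in a single compartment.

Nine conductances follow the Hodgkin–Huxley template
`I = ḡ mˣ hʸ (V − E)`, with each gate relaxing as
`dm/dt = (m∞ − m)/τ` toward a Boltzmann steady state
`m∞ = 1/(1 + exp((V + V½)/S))`; a negative slope factor S makes the sigmoid
increase with depolarization (activation), a positive one decrease
(inactivation) — the sign is always explicit in the configuration and never
flipped silently. The gates of the small- and intermediate-conductance
Ca²⁺-activated K⁺ channels (SK, IK) instead track a Hill function of
intracellular calcium, `m∞ = 1/(1 + (Ca½/Cai)ⁿ)`, the same functional form
used for TRPM4 activation. Time constants may be voltage tables
(piecewise-linear, flat extrapolation); the shipped model uses constants.

The BK channel is a ten-state Markov chain — closed states C0–C4 and open
states O0–O4 on two Ca²⁺-binding ladders joined by voltage-dependent C↔O
transitions — with `I_BK = ḡ_BK (O1+O2+O3+O4)(V − E_K)`. The published rate
table fixes the ladder rates (multiples of K_on = 335 binding, K_coff =
K_ooff = 26 unbinding) and the ten base C↔O rates; the voltage factors `a`
(forward) and `b` (backward) are given no functional form in the source, so
the package models them as `a = exp(V/σ_a)`, `b = exp(−V/σ_b)` with e-fold
slopes σ defaulting to 9 mV in the whole-cell model (hyperpolarization
favours closure). A `conducting_states` switch allows the O4-only reading of
the conducting set.

Two points about the BK rate table deserve emphasis. First, taken verbatim,
the table multiplies the *unbinding* rates (and the closing rate K_O4C4) by
`cai`. Calcium then cancels from every binding/unbinding ratio and survives
only in K_O4C4, so the steady-state open probability of the verbatim table
*decreases* with calcium — the opposite of a Ca²⁺-activated channel.
`bk_params(ca_unbinding = "printed")` reproduces that table exactly;
`"canonical"` drops the spurious `cai` factors (the standard form of this
ten-state BK lineage) and restores monotone calcium activation. The shipped
whole-cell model uses the canonical form, because a BK channel that closes on
calcium influx cannot play its repolarizing role; both forms are unit-tested.
Second, the occupancy update uses an exact matrix exponential of the frozen
generator each step rather than an implicit linear solve: the generator is
stiff (rates spanning ~10⁻³–10³ ms⁻¹) and the exponential propagator is
unconditionally stable *and* exact at frozen (V, Cai), which a backward-Euler
step is not (its per-step error on the ~1 ms⁻¹ modes is of order 10⁻³).

TRPM4 is a calcium-activated non-selective cation channel,
`I = ḡ m (V − E_rev)` with `E_rev = −40 mV`, a single activation gate (the
source text mentions inactivation but defines none; an optional inactivation
slot exists in the configuration and defaults to absent), Hill steady state
in calcium and a first-order time constant. Because its reversal sits between
rest (−52 mV) and spike threshold, TRPM4 depolarizes the resting membrane and
acts as a plateau current pulling toward −40 mV — and, importantly, it
*self-limits*: its driving force vanishes as the membrane approaches −40 mV.

Intracellular calcium follows a minimal submembrane pool,
`dCai/dt = −I_Ca/(2F·depth) − (Cai − Ca_rest)/τ_removal`, fed by the CaT and
CaL currents, with `Ca_rest = 150 nM`, an effective shell depth of 1 µm and
τ_removal = 5 ms (both effective, non-measured parameters). With a standing
window calcium current the pool equilibrates slightly above the extrusion
target (≈0.4 µM at rest in the shipped model); this emergent offset is a
property of the stated pool equation, not an error, and the Ca²⁺-dependent
parameters were calibrated against the realized concentration. `clamp = TRUE`
holds the pool at `Ca_rest` exactly for experiments that assume strictly
constant calcium.

## Integration

The membrane equation is advanced with a fixed step (default dt = 0.04 ms)
and operator splitting: (1) the calcium pool updates by its exact
exponential solution at frozen influx; (2) every HH gate updates by the exact
exponential relaxation at frozen voltage and pre-step calcium; (3) the BK
occupancy updates by the exact matrix exponential at frozen (V, Cai); (4) the
voltage updates by backward Euler on the ohmic current sum with the updated
conductances — the alpha-synapse conductance enters the implicit step, so
synaptic drive cannot destabilize it. Everything is deterministic;
repeated runs are bit-identical, and a run of 1000 ms equals the first half
of a run of 2000 ms exactly. A step that carries |V| beyond 200 mV raises an
integration-failure error naming the step. Self-convergence is first order in
dt as expected for the voltage sub-step; at the default step the subthreshold
trace differs from a dt/4 reference by well under 0.5 mV. Spike *timing*
near threshold is exponentially sensitive to perturbations in any
excitable-membrane model, so pointwise convergence statements are made on
resting and subthreshold traces, and spiking traces are compared through
their extracted features.

## Calibration: what is given and what is fitted

The published description fixes the geometry, the passive constants, the
maximum conductances (CaT 2, CaL 3, Kv1 6, KDR 9, BK 8, IK 7, SK 1, KATP 1,
KIR 1, TRPM4 2, all ×10⁻⁴ S/cm²), dt, E_Na(TRPM4) = −40 mV, the BK rate
table, and the whole-cell outcomes: resting potential −52 mV held for
2000 ms, a 10-ms pulse threshold printed as "0.56", a synaptic threshold of
0.0079 µS, and AP threshold voltages of −38.56 mV (pulse) and −38.42 mV
(synapse). Every gating parameter (V½, S, τ) is inherited from earlier work
without being reprinted, so in this package they are *calibration
parameters*: chosen by a staged numerical workflow (steady-state balance
analysis, Nelder–Mead exploration, then nested one-dimensional solves) so
that the assembled cell reproduces the printed outcomes, with the published
conductances as the centre of ±30% bounds (CaT and CaL ship at +30%, the
rest at their published values). The same workflow is exposed to users as
[calibrate_cell()], a deterministic bounded coordinate descent over maximum
conductances against the same target set.

Decisions made where the design was genuinely open:

* **Stimulus units.** The printed pulse threshold "0.56 mA" is unphysical
  for a 37.7 pF cell, so amplitudes are raw numbers in a configurable unit.
  A 0.56 nA rheobase would force a ~24 MΩ input resistance — two orders of
  magnitude below an isolated DSM cell — and the Table-1 K⁺ conductances
  would then crush the Ca²⁺ spike. The shipped protocol therefore uses a
  0.1 nA unit: rheobase 0.56 units = 56 pA, input resistance ≈ 1.4 GΩ, both
  physiological. `pulse_stimulus()` itself defaults to 1 nA units; the
  calibrated protocol lives in `default_pulse_protocol()`.
* **Reversal potentials.** E_K = −75 mV and E_Ca = +80 mV (the calcium
  Nernst potential for ~2 mM external / sub-µM internal calcium exceeds
  +100 mV; +80 mV is a conventional effective value). The ohmic leak's
  reversal (+156 mV at the published leak conductance of 1/138 mS/cm²) is an
  effective lumped background — it represents the small standing Na⁺/cation
  inward current that holds −52 mV against the K⁺ channels, expressed
  through the fixed published membrane resistivity.
* **Channel roles.** CaT (activation midpoint −33 mV) supplies the
  low-threshold window current that carries the membrane toward threshold;
  CaL (midpoint ≈ −33.7 mV, steep slope 3.5 mV, τ 0.6 ms) carries the
  regenerative upstroke; Kv1 is A-type — fast activation around −33.6 mV
  with steep inactivation near −39 mV — so it brakes the subthreshold
  approach (setting the 56 pA rheobase) and then releases right at spike
  takeoff, sharpening the threshold; KDR (midpoint −5 mV, τ 10 ms) is the
  main repolarizer; BK, SK (Ca½ 0.7 µM, τ 30 ms) and IK (Ca½ 2.5 µM,
  τ 40 ms) shape repolarization and the after-hyperpolarization; KIR and
  KATP set the resting K⁺ background.
* **AP threshold criterion.** The threshold voltage is read at the last
  upward crossing of a dV/dt criterion before the spike peak (the onset of
  the final regenerative excursion; a first-crossing rule would read the
  stimulus artifact instead). The criterion default, 1.9 mV/ms, is itself a
  calibrated quantity: the model's just-suprathreshold APs leave the
  saddle-point creep at about that rate of rise, and with this value the
  pulse- and synapse-derived thresholds read −38.3 and −38.6 mV at their
  just-suprathreshold amplitudes, agreeing within 0.5 mV.
* **Synaptic protocol.** The alpha-function time constant is calibrated to
  0.4124 ms with a 0 mV reversal: the threshold charge of the cell
  (≈0.6 pC) and the printed 0.0079 µS threshold conductance jointly pin the
  kinetics to a fast, brief transient. `default_syn_protocol()` carries it.
* **Initialization and settling.** Gates start at their steady states for
  −52 mV and the calcium target; since the pool equilibrates slightly above
  the target, an initial transient of a few hundred milliseconds follows
  (`equilibrate = TRUE` pre-runs the model to its exact fixed point
  instead). Reported features discard a 500-ms settling window by default.

## The synthetic activation-curve generator

TRPM4 steady-state activation data (for [fit_hill()]) are emulated by
[simulate_activation_curve()]: calcium sampled uniformly in log₁₀ space over
10⁻⁵–10⁻¹ mM, activation from the Hill equation at stated (Ca½, n), plus
additive Gaussian noise (default SD 0.02), clipped to [0, 1], under a fixed
seed. This reproduces the geometry of digitized steady-state activation
measurements — a sigmoid in log-calcium with roughly uniform scatter. It does
not emulate systematic digitization bias, calcium-buffering artifacts, or
rundown, so a passing fit-recovery test demonstrates estimator correctness,
not robustness to those real-data effects. The fit itself is bounded least
squares with a fixed multi-start grid (deterministic), reporting the
degrees-of-freedom-corrected RMSE `S = sqrt(Σ(y_exp − y_sim)²/(M − N))` and
the strict 5%-of-range verdict.

## Known limitations

* Only spike-type action potentials are represented; pacemaking-type
  activity, multicellular coupling and contraction are out of scope.
* The calcium pool is a single effective shell; there is no SR store, IP₃
  signalling or buffering, so agonist-evoked calcium release can only be
  imitated by clamping or by external stimuli.
* With the published TRPM4 reversal of −40 mV the channel self-limits
  between rest and its equilibrium: conductance elevations shift the resting
  potential monotonically toward −40 mV (the sensitivity sweep shows
  ≈ +1 mV across −30%…+20%) but cannot destabilize the action potential in
  this calibration — at +20% the AP repolarizes and returns to rest like the
  baseline, and far larger elevations make the cell *less* excitable
  (depolarization-inactivated CaT plus added membrane load). A reported
  instability at +20% is therefore not reproduced by these equations; the
  non-physiological flag (no return to within 10 mV of rest within 500 ms,
  or a secondary spike after the stimulus) is implemented and exercised on
  constructed traces, but the shipped model never trips it in the sweep.
* The model is deterministic; the natural variability of DSM AP shapes is
  representable only through parameter changes.

## Problem sizes used by the test suite

The suite simulates at the model's native dt = 0.04 ms: a 2000-ms resting
run for the hold test, 1000-ms runs per threshold probe (about ten probes
per bisection), 1200-ms runs for the six-point sensitivity sweep and the
knockout pair, and short (50–400 ms) runs for the numerical property checks;
BK oracle comparisons use the full 10×10 generator, and fit-recovery runs 20
seeded datasets of 30 points. The complete suite finishes in well under a
minute on one CPU.
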