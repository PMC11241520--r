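# dsmcell

Biophysical simulation of detrusor smooth muscle (DSM) cell excitability in R.

DSM cells in the urinary bladder wall fire Ca²⁺-driven action potentials
(APs); their excitability is shaped by an unusual mix of depolarizing and
repolarizing conductances, and hyperexcitability underlies overactive
bladder syndrome. `dsmcell` implements a single-compartment model of an
isolated DSM cell for studying how the Ca²⁺-activated TRPM4 cation channel
modulates resting potential, AP threshold and AP shape, and how other
channels can compensate when one is lost.

## The model

A cylindrical cell (200 µm × 6 µm, Cm = 1 µF/cm², lateral area only) carries
eleven membrane currents in parallel:

* **Nine Hodgkin–Huxley-type conductances** — T-type (CaT) and L-type (CaL)
  Ca²⁺ channels, fast (Kv1) and delayed-rectifier (KDR) K⁺ channels, inward
  rectifier (KIR), ATP-sensitive K⁺ (KATP), small- and
  intermediate-conductance Ca²⁺-activated K⁺ channels (SK, IK), and an ohmic
  leak. Each gate follows first-order kinetics
  `dm/dt = (m∞(V) − m)/τ` with a Boltzmann steady state
  `m∞ = 1/(1 + exp((V + V½)/S))` (SK/IK gates follow a Hill function of
  intracellular Ca²⁺ instead), and each current is
  `I = ḡ mˣ hʸ (V − E)`.
* **A 10-state Markov BK channel** — five closed (C0–C4) and five open
  (O0–O4) states on two Ca²⁺-binding ladders joined by voltage-dependent
  C↔O transitions (`a = e^{V/25..9 mV}` forward, `b = e^{−V/9 mV}` back);
  `I_BK = ḡ_BK · (O1+O2+O3+O4) · (V − E_K)`. Occupancy is propagated each
  step with an exact matrix exponential of the generator.
* **TRPM4** — a Ca²⁺-activated non-selective cation channel,
  `I = ḡ m (V − E_rev)` with `E_rev = −40 mV` and Hill steady-state
  activation `m∞ = 1/(1 + (Ca½/Cai)ⁿ)`; it carries depolarizing current at
  rest and closes the positive-feedback loop between Ca²⁺ entry and
  depolarization.
* **A submembrane Ca²⁺ pool** supplying `Cai` to BK/SK/IK/TRPM4:
  `dCai/dt = −I_Ca/(2F·depth) − (Cai − Ca_rest)/τ_removal` with
  `Ca_rest = 150 nM`.

The membrane equation is integrated with an operator-split implicit scheme
(exact exponential gate updates + backward-Euler voltage update) at
`dt = 0.04 ms`. Maximum conductances are centred on the published whole-cell
values (e.g. BK 8e-4, CaL 3e-4, TRPM4 2e-4 S/cm²); gating kinetics are
calibration parameters of this package, tuned so the assembled cell rests at
−52 mV, has a 10-ms pulse rheobase of 0.56 stimulus units (0.1 nA units,
i.e. 56 pA) and an alpha-synapse threshold of 0.0079 µS, and fires from a
threshold near −38.5 mV. See the methods vignette
(`vignettes/dsm-cell-model.Rmd`) for every choice and its rationale.

## Worked example

```r
library(dsmcell)

model <- default_dsm_model()

## resting behaviour: 2000 ms, no stimulus
rest <- simulate_cell(model, stimulus = NULL, t_stop = 2000)
mean(rest$v[rest$t >= 500])   # settled resting potential, mV

## just-suprathreshold pulse and its AP features
tr <- simulate_cell(model, default_pulse_protocol(0.56), t_stop = 1000)
extract_features(tr)

## rheobase by bisection (raw amplitude, 0.1 nA units)
threshold_search(model, "pulse", lo = 0.2, hi = 1.4, resolution = 0.01,
                 unit_nA = 0.1)

## TRPM4 conductance sensitivity, -30% .. +20%
sweep <- conductance_sweep(model, "trpm4",
                           factors = seq(0.7, 1.2, by = 0.05),
                           stimulus = default_pulse_protocol(0.8))
sweep[, c("factor", "rmp", "spike", "nonphysiological")]
```

On the shipped calibrated model the resting trace settles at −52.01 mV
(band well inside ±1 mV from 500 ms on), the pulse search returns 0.56
(amplitude 0.55 does not spike) with an AP threshold voltage of −38.32 mV,
and the synaptic search (`kind = "alpha"`, `tau_alpha = 0.4124`, resolution
0.0001) returns 0.0079 µS (0.0078 does not spike) with a threshold voltage
of −38.57 mV — the two threshold voltages agree within 0.25 mV. The sweep
fires at every factor with a clean return to rest, and its resting-potential
column rises monotonically with the TRPM4 conductance (−54.8 mV at −30% to
−50.9 mV at +20%); because the TRPM4 reversal of −40 mV self-limits the
channel's depolarizing feedback, the +20% run remains physiological here
(see the vignette's limitations section). Muting the T-type conductance
abolishes the AP at the 0.56 stimulus, and the shipped TRPM4/CaL/KIR
compensation set (`default_cat_compensation()`) restores it.

A thin CLI over the same functions ships in `inst/cli/dsmcell.R`
(`simulate`, `features`, `threshold-search`, `sweep`, `knockout`,
`fit-activation`, `calibrate`, `make-fixtures`).

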