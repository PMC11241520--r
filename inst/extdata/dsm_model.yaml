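geometry:
  length_um: 200.0
  diameter_um: 6.0
passive:
  c_specific_uF_cm2: 1.0
  r_membrane_kohm_cm2: 138.0
  r_cytoplasm_ohm_cm: 183.0
calcium:
  ca_rest_mM: 0.00015
  tau_removal_ms: 5.0
  depth_um: 1.0
  clamp: no
channels:
  cat:
    gmax_S_cm2: 0.00026
    e_rev_mV: 80.0
    carries_ca: yes
    activation:
      kind: boltzmann
      v_half_mV: 33.0
      slope_mV: -5.5
      tau_ms: 2.0
      power: 1
    inactivation:
      kind: boltzmann
      v_half_mV: 46.0
      slope_mV: 5.0
      tau_ms: 25.0
      power: 1
    provenance: calibrated
  cal:
    gmax_S_cm2: 0.00039
    e_rev_mV: 80.0
    carries_ca: yes
    activation:
      kind: boltzmann
      v_half_mV: 33.664363000000002
      slope_mV: -3.5
      tau_ms: 0.6
      power: 1
    inactivation:
      kind: boltzmann
      v_half_mV: 42.0
      slope_mV: 9.0
      tau_ms: 60.0
      power: 1
    provenance: calibrated
  kv1:
    gmax_S_cm2: 0.0006
    e_rev_mV: -75.0
    activation:
      kind: boltzmann
      v_half_mV: 33.570114940000003
      slope_mV: -6.0
      tau_ms: 2.0
      power: 1
    inactivation:
      kind: boltzmann
      v_half_mV: 39.0
      slope_mV: 3.0
      tau_ms: 1.5
      power: 1
    provenance: calibrated
  kdr:
    gmax_S_cm2: 0.0009
    e_rev_mV: -75.0
    activation:
      kind: boltzmann
      v_half_mV: 5.0
      slope_mV: -9.0
      tau_ms: 10.0
      power: 1
    provenance: calibrated
  kir:
    gmax_S_cm2: 0.0001
    e_rev_mV: -75.0
    activation:
      kind: boltzmann
      v_half_mV: 65.0
      slope_mV: 10.0
      tau_ms: 1.0
      power: 1
    provenance: calibrated
  katp:
    gmax_S_cm2: 0.0001
    e_rev_mV: -75.0
    provenance: paper
  sk:
    gmax_S_cm2: 0.0001
    e_rev_mV: -75.0
    activation:
      kind: hill
      ca_half_mM: 0.000707945784384
      hill_n: 4.0
      tau_ms: 30.0
      power: 1
    provenance: paper
  ik:
    gmax_S_cm2: 0.0007
    e_rev_mV: -75.0
    activation:
      kind: hill
      ca_half_mM: 0.00251188643151
      hill_n: 4.0
      tau_ms: 40.0
      power: 1
    provenance: paper
  leak:
    gmax_S_cm2: 7.246376811594203e-06
    e_rev_mV: 156.278312999999997
    provenance: calibrated
  bk:
    gmax_S_cm2: 0.0008
    e_k_mV: -75.0
    k_on: 335.0
    k_coff: 26.0
    k_ooff: 26.0
    co_rates:
    - 0.03162
    - 0.000969
    - 3.81e-05
    - 8.809999999999999e-04
    - 5.4324e-02
    oc_rates:
    - 328.108400000000017
    - 154.173599999999993
    - 33.659399999999998
    - 0.097312
    - 0.000406
    a_efold_mV: 9.0
    b_efold_mV: 9.0
    conducting_states:
    - O1
    - O2
    - O3
    - O4
    ca_unbinding: canonical
    provenance: paper
  trpm4:
    gmax_S_cm2: 0.0002
    e_rev_mV: -40.0
    ca_half_mM: 0.000398107170553
    hill_n: 1.5
    tau_m_ms: 50.0
    power: 1
    provenance: paper
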