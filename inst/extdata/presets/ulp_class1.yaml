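# Ultralow-power two-variable neuron, Class-I-like mode.
# Derived by seeded random search + verification (three equilibria:
# stable / saddle / unstable; excitable, silent at rest). The onset is
# hysteretic (saddle-loop): the down-sweep sustained frequency falls
# continuously to ~16% of the ~490 Hz plateau, far below the Class II
# preset's ~75% onset ratio. Stimulus headroom ~0.22 nA (sustained).
family: ulp_sn
params:
  C_v: 1.5 pF
  C_n: 2.0 pF
  I_av: 0.563 nA
  I_an: 0.153 nA
  I_0P: 2e-14
  M_v: 3.736 nA
  delta_v: 0.476 V
  R_v20: 1
  R_v21: 1
  theta_v: 0.442 V
  M_n: 5.878 nA
  delta_n: 0.598 V
  R_n20: 1
  R_n21: 1
  theta_n: 0.239 V
  theta_r: 0.421 V
  U_T: 0.026 V
  kappa: 0.7
attributes:
  spike_threshold: 0.50 V   # rest 0.421 V + margin
  I_max: 0.22 nA          # sustained-stimulus headroom
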