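# Ultralow-power two-variable neuron, Class II mode.
# Derived by seeded random search + verification (equilibrium validity
# requires the recovery current at the fixed point to lie inside the open
# range of r). Single stable equilibrium at rest; spiking terminates at a
# nonzero minimum frequency; spike peak grows monotonically with pulse
# amplitude (graded response). Sustained-stimulus headroom ~0.9 nA.
family: ulp_sn
params:
  C_v: 1.5 pF
  C_n: 2.0 pF
  I_av: 1.4294 nA
  I_an: 0.1502 nA
  I_0P: 2e-14
  M_v: 3.3963 nA
  delta_v: 0.5359 V
  R_v20: 1
  R_v21: 1
  theta_v: 0.4429 V
  M_n: 3.5354 nA
  delta_n: 0.5681 V
  R_n20: 1
  R_n21: 1
  theta_n: 0.352 V
  theta_r: 0.4446 V
  U_T: 0.026 V
  kappa: 0.7
attributes:
  spike_threshold: 0.52 V   # rest + ~0.08 V margin
  I_max: 0.9 nA             # sustained-stimulus headroom
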