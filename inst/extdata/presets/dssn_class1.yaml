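# Digital spiking silicon neuron, Class I excitability.
# Derived with the package's mode-tuning workflow (geometry search +
# verification by find_equilibria / fi_curve / classify_excitability,
# seed 1) and frozen. Three equilibria (stable node / saddle / unstable
# focus) at rest; saddle-node-on-invariant-circle onset near I_stim = 0.05;
# minimum sustained frequency ~4 Hz = 6% of the ~64 Hz plateau.
family: dssn
params:
  phi: 2.0
  tau: 0.003
  I_0: 0.0
  a_fn: 2.0
  b_fn: -0.5
  c_fn: 0.0
  a_fp: -2.0
  b_fp: 0.5
  c_fp: 1.0
  a_gn: 0.5
  b_gn: -0.5
  c_gn: 0.05
  a_gp: 10.0
  b_gp: 0.0
  c_gp: 0.175
  r_g: 0.0
attributes:
  spike_threshold: 0.0
  sustained_I: 0.1        # ~35 Hz repetitive spiking for network runs
  c_scale: 0.02           # accumulator scaling (network characterization)
  I_snic: 0.05            # saddle-node-on-invariant-circle stimulus
  I_plateau: 0.25         # upper end of the characterized f-I range
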