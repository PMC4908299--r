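# Digital spiking silicon neuron, Class II excitability.
# Derived with the package's mode-tuning workflow and frozen. Single
# stable-focus equilibrium at rest; subcritical Hopf near I_stim = 0.51
# with a fold of limit cycles near 0.49 (bistable window between);
# onset frequency ~64 Hz = 90% of plateau; strongly graded pulse
# responses. The recovery nullcline saturates high (c_gp) so the
# repetitive-spiking stimulus band extends to ~1.1 before depolarization
# block, which the all-to-all network runs rely on.
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
  a_gn: 2.0
  b_gn: -0.9
  c_gn: 0.0
  a_gp: -0.5
  b_gp: 2.1
  c_gp: 3.6
  r_g: -0.3
attributes:
  spike_threshold: 0.0
  sustained_I: 0.7        # ~64 Hz repetitive spiking for network runs
  c_scale: 0.012
  I_hopf: 0.51            # subcritical Hopf stimulus (approximate)
  I_fold: 0.49            # fold-of-cycles stimulus (bistable window start)
  I_probe_lo: 0.4         # f-I sweep bracket used in characterization
  I_probe_hi: 1.0
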