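# Three-variable analog silicon neuron, autonomous square-wave bursting.
# Derived with the package's tuning workflow and frozen. Fast (v, n)
# subsystem: three equilibria with the rest state lost via saddle-node
# near q = 28 pA and the spiking cycle lost via saddle-loop near
# q = 30.5 pA (bistable window between). The q-nullcline separates the
# rest state from the cycle: bursts of ~6 spikes alternate with ~100 ms
# silences. Sweeping M_q reproduces tonic spiking -> chaotic bursting
# (near 122 pA) -> regular bursting with the spike count per burst
# decreasing toward single-spike bursting.
family: analog_sn
params:
  C_v: 0.5 pF
  I_a: -25 pA
  tau_n: 1.2 ms
  tau_q: 0.8 s
  M_m: 300 pA
  delta_m: 0 V
  M_n: 140 pA
  delta_n: 0.02 V
  M_q: 150 pA
  delta_q: 0.04 V
  S: 200 pA
  theta_v: -0.04 V
  U_T: 0.026 V
  kappa: 0.7
attributes:
  spike_threshold: 0.0
  q_burst_lo: 28 pA       # saddle-node of the fast subsystem
  q_burst_hi: 31 pA       # saddle-loop of the fast subsystem
  Mq_sweep_lo: 100 pA     # characterized regime-sweep range
  Mq_sweep_hi: 260 pA
  Mq_chaotic: 122 pA      # aperiodic spike-count band
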