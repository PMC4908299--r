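# qsn — qualitative-modeling-based silicon neurons

`qsn` implements, in software, a family of silicon neuron models designed
by qualitative modeling: instead of reproducing ionic conductances, each
model reproduces the *dynamical structure* of a neuronal class —
nullcline geometry, equilibria, and bifurcations — using the idealized
V–I curves of subthreshold CMOS circuit blocks as its building material.
It is aimed at computational neuroscientists and neuromorphic engineers
who want to study these circuit models, configure them into specific
excitability classes, and run the spiking associative-memory experiments
they support.

Three models are implemented:

* **Analog silicon neuron** (3 variables): membrane equation
  `C_v dv/dt = -g(v) + f_m(v) - n - q + I_a + I_stim` with
  differential-pair sigmoids `f_x(v) = M_x / (1 + exp(-(κ/U_T)(v-δ_x)))`,
  a shallower transconductance tanh `g(v)`, and first-order (Tau-cell)
  gating for the fast (`n`) and slow (`q`) currents. Supports Class I/II
  excitability, regular spiking, and square-wave bursting.
* **Ultralow-power silicon neuron** (2 variables): capacitor-voltage
  state `(v, n)` with a shared recovery sigmoid `r(n)`, plus the exactly
  equivalent `(v, ñ)` formulation with `ñ ≡ r(n)`.
* **Digital spiking silicon neuron (DSSN)**: piecewise-quadratic
  two-variable model solved by forward Euler (375 µs network step),
  optionally in emulated two's-complement fixed-point arithmetic with
  per-operation quantization.

Around the models sits a dynamics toolkit — equilibria with analytic
Jacobians and stability labels, sweep-and-detect bifurcation diagrams
(saddle-node, SNIC, subcritical Hopf, saddle-loop, fold of cycles), f–I
curves with Hodgkin classification, graded-response probes, burst
segmentation, a period-doubling/chaos sweep, and a seeded annealing mode
tuner — plus kinetic silicon synapses, exponential (Mexican-hat) STDP,
correlation storage, and a 256-neuron all-to-all associative memory with
circular-order-parameter retrieval metrics (`M_u`, `PSI`).

## A worked example

Load the frozen Class I digital preset, look at its phase-plane
structure, and classify its excitability:

```r
library(qsn)

m <- qsn_preset("dssn_class1")
find_equilibria(m)
#>            v          n   eig1_re  eig1_im   eig2_re   eig2_im          label
#> 1 -0.6825742 0.06666667 -194.5415   0.0000 -625.6563    0.0000    stable_node
#> 2 -0.3174258 0.06666667  433.9897   0.0000 -280.4585    0.0000       saddle
#> 3  0.2677995 0.89216588  142.9340 981.5241  142.9340 -981.5241 unstable_focus
#>       residual
#> 1 1.387779e-17
#> 2 1.387779e-17
#> 3 0.000000e+00
```

Three equilibria — a stable rest state, a saddle whose stable manifold is
the spike threshold, and an unstable focus — the classic Class I
geometry. Sweeping the stimulus past the saddle-node (`I_stim ≈ 0.050`)
produces repetitive spiking whose frequency rises from near zero:

```r
fi <- fi_curve(m, I_values = 0.05 + seq(4e-4, 4e-3, by = 4e-4), T_run = 4)
round(fi$freq)
#>  [1]  5  7  8  9 10 11 11 12 13 13
```

A 5 Hz onset against a ~64 Hz plateau (8%, below the 10% Class I
criterion), rising smoothly as the stimulus leaves the saddle-node
ghost. The Class II
preset (`qsn_preset("dssn_class2")`) instead starts at ~57 Hz through a
subcritical Hopf with a bistable window, and its spike peaks grade with
stimulus amplitude.

Retrieval in the associative network:

```r
pats <- generate_patterns(256, 4, seed = 1)       # four stored patterns
W    <- correlation_weights(pats)                  # Hopfield outer product
cfg  <- retrieval_config(mode = "class2")
inp  <- flip_pixels(pats[[1]], 0.10, seed = 7)     # corrupt 26 pixels
r    <- simulate_assoc_network(W, pats, inp, cfg, correct_u = 1)
tail(r$metrics[, c("t", "M_1", "M_2", "PSI2")], 1)
#>        t       M_1        M_2      PSI2
#> 584 2.92 0.8356512 0.05566389 0.4429132
r$success
#> [1] TRUE
```

The overlap with the corrupted pattern's original (`M_1`) rises above
0.8 and holds there while the other overlaps stay low — the pattern is
retrieved from a 10% corrupted cue. `error_sweep()` runs the full
protocol (error levels 5–50%, ten seeded trials each) and tabulates
success rates.

## Command-line use

A thin wrapper over the package functions ships at `inst/cli/qsn.R`:

```sh
QSN=$(Rscript -e 'cat(system.file("cli/qsn.R", package = "qsn"))')
Rscript $QSN simulate   --config cfg.yaml --out out/
Rscript $QSN nullclines --config cfg.yaml --out out/
Rscript $QSN bifurcate  --config cfg.yaml --param q --range 2e-11:4e-11:30 --out out/
Rscript $QSN ficurve    --config cfg.yaml --range 0:0.3:20 --out out/
Rscript $QSN assocmem   --mode class2 --error 0.10 --trials 10 --seed 1 --out out/
Rscript $QSN selftest
```

Configurations are YAML with blocks `analog_sn`, `ulp_sn`, `dssn`,
`synapse`, `stdp`, `experiment`; quantities may carry unit suffixes
(`"375 us"`, `"60 pA"`), normalized to SI on load. Every run writes a
manifest capturing the resolved configuration and seed.

## Package layout

* `R/` — models (`analog.R`, `ulp.R`, `dssn.R`), dynamics toolkit
  (`dynamics-*.R`), synapses/learning (`synapse.R`), network
  (`network.R`, `patterns.R`), interface (`config.R`, `presets.R`,
  `cli.R`).
* `src/` — the fixed-step integration loops (RK4, quantized Euler, the
  network co-simulation, batch STDP) in Rcpp.
* `inst/extdata/presets/` — frozen mode presets (YAML) with their
  derivation provenance and characterization numbers.
* `vignettes/silicon-neurons.Rmd` — the methods vignette: model
  equations and assumptions, how the presets were derived, numerical
  choices, the retrieval protocol, and known limitations.
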