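---
title: "Qualitative-modeling-based silicon neurons: models, analysis, and the associative network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Qualitative-modeling-based silicon neurons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsn)
```

## The modeling idea

Qualitative neuron models reproduce the *dynamical structure* of
electrophysiological activity — the arrangement of nullclines, equilibria
and limit cycles in phase space — rather than the biophysical detail of
ionic conductances. This package implements three such models whose
right-hand sides are built from "device-native" formulae, the idealized
V–I curves of subthreshold CMOS circuit blocks, plus the analysis toolkit
needed to place each model in a desired dynamical class.

### The three-variable analog membrane

$$C_v \dot v = -g(v) + f_m(v) - n - q + I_a + I_{stim}, \qquad
  \dot n = \frac{f_n(v)-n}{\tau_n}, \qquad
  \dot q = \frac{f_q(v)-q}{\tau_q}$$

with differential-pair sigmoids
$f_x(v) = M_x/(1+e^{-(\kappa/U_T)(v-\delta_x)})$ and the shallower
transconductance-amplifier curve
$g(v) = S\tanh\!\big(\tfrac{\kappa}{2U_T}(v-\theta_v)/(1+1/\kappa)\big)$.
The thermal voltage $U_T \approx 26\,$mV and coupling ratio
$\kappa \approx 0.7$ fix the steepness of every curve, so the designer's
freedom is in the amplitudes and midpoints. Because $g$ is shallower than
$f_m$, their difference can be N-shaped, and the v-nullcline
$n = f_m(v) - g(v) - q + I_a + I_{stim}$ supports the full repertoire of
two-dimensional spike-generation structures with $q$ acting as a slow
inhibitory sweep. The first-order integrations of $n$ and $q$ correspond
to current-mode Tau-cell integrators, $\dot I_{out} =
(I_{in}-I_{out})/(C\,U_T/I_\tau)$, for which `tau_cell_response()` uses
the exact piecewise-exponential solution.

A note on the v-nullcline: with the slow current present the nullcline is
$n = f_m - g - q + I_a + I_{stim}$; at $q=0$ this reduces to the commonly
quoted form without the $-q$ term. `analog_nullclines()` always includes
$-q$, treating $q$ as the fast subsystem's parameter, which is the view
`fast_subsystem()` and the bifurcation sweeps take.

### The two-variable ultralow-power membrane

$$C_v\dot v = f_v(v) - g_v(v) + I_{av} - r(n) + I_{stim}, \qquad
  C_n\dot n = f_n(v) - g_n(v) + I_{an} - r(n)$$

Both state variables are capacitor voltages; the recovery current flows
through a shared sigmoid $r(n)$ whose plateau is
$I_{0P}e^{(\kappa/U_T)\theta_r}$. Since $r$ is strictly increasing, the
substitution $\tilde n \equiv r(n)$ produces an equivalent system on the
$(v,\tilde n)$ plane with
$C_n\dot{\tilde n} = r'(n)\,(f_n - g_n + I_{an} - \tilde n)$; the package
integrates either chart and the test suite asserts their agreement. The
cascode curve $r$ is written as a function of the recovery voltage $n$;
the printed source formula carries a stray $v$ in the exponent, which the
transform and its $r'(n)$ factor show must be $n$ — we implement it that
way and treat the $v$ as a typo. The inverse $r^{-1}$ is the closed-form
logit, never a numerical root.

Two boundedness facts shape every usable parameter set, and the shipped
presets respect both. First, the membrane equation is only confined if
$M_v + I_{av} + I_{stim}$ stays below the sum of the $g_v$ saturation and
the $r$ plateau; the headroom above the v-nullcline maximum is the usable
sustained-stimulus range (recorded per preset as `I_max`). Second, a root
of the scalar equilibrium condition is a genuine fixed point only when
the recovery current it requires lies strictly inside the open range of
$r$; `find_equilibria()` rejects roots that violate this, because outside
it the recovery voltage drifts without a fixed point even though the
reduced scalar condition has a sign change.

### The digital spiking neuron (DSSN)

$$\dot v = \frac{\phi}{\tau}\,(f(v) - n + I_0 + I_{stim}), \qquad
  \dot n = \frac{g(v) - n}{\tau}$$

with $f$ and $g$ piecewise quadratic ($a(v-b)^2+c$ on each branch,
breakpoints at $0$ and $r_g$). The piecewise-quadratic $f$ realizes the
N-shaped v-nullcline with a single constant-times-variable multiply per
branch, which is the hardware motivation. The model is integrated by
forward Euler — 375 µs steps in the network experiments — optionally in
emulated two's-complement fixed point: every multiply and add result is
quantized once (`truncate` drops low bits like a shifter; saturation is
the default overflow policy). The default 18-bit/10-fraction word is a
typical FPGA choice, not a claim about any particular chip; the
characterization runs freeze its trajectory error (0.0075 on the
subthreshold reference run, phase-slip-bounded 0.5 on a spiking run) and
the tests assert the error is non-increasing in the number of fractional
bits.

## Mode presets and how they were derived

None of the mode parameter values are published, so the presets shipped
under `inst/extdata/presets/` were derived with the package's own
workflow — `tune_mode()`'s annealing search over the geometry penalties
plus explicit verification by `find_equilibria()`, `fi_curve()`,
`classify_excitability()`, `sweep_bifurcation()` and the burst checks —
and then frozen as YAML fixtures with their characterization numbers.
The headline presets:

* `dssn_class1` — three equilibria (stable node, saddle, unstable
  focus); spiking onset through a saddle-node on invariant circle near
  $I_{stim}=0.050$; the measured period exponent on approach is
  $\approx -0.45$, and the sustained frequency can be brought below 6% of
  the ~64 Hz plateau.
* `dssn_class2` — a single stable focus; a subcritical Hopf near
  $I_{stim}=0.51$ preceded by a fold of limit cycles near $0.49$
  (bistable window between); onset at ~90% of the plateau frequency;
  strongly graded pulse responses (~75× the Class I spread). Its
  recovery nullcline saturates high so the repetitive-spiking band
  reaches $I_{stim}\approx 1.1$ before depolarization block — the
  network experiments need that headroom.
* `analog_square_wave` — the fast subsystem loses its rest state via a
  saddle-node near $q = 28$ pA and its spiking cycle via a saddle-loop
  near $q \approx 29$–30 pA (the log-divergence fit of the period against
  the fitted homoclinic point gives $R^2 \approx 0.98$). With
  $\tau_q = 0.8$ s the full model bursts autonomously; sweeping $M_q$
  reproduces tonic spiking, a narrow chaotic band near 122 pA (certified
  by aperiodic spike counts over ≥40 bursts *and* trajectory
  decorrelation under a $10^{-9}$ V perturbation), then regular bursting
  whose spike count per burst decreases toward one.
* `ulp_class1` / `ulp_class2` — the two-variable membrane in a
  three-equilibrium excitable mode and a single-equilibrium graded mode.
  Under the fixed fabricated capacitances (1.5/2.0 pF) the recovery
  speed is pinned to the membrane speed, and our search (~10⁵
  candidates) found no true SNIC; the Class-I-like preset instead has a
  hysteretic saddle-loop onset whose down-sweep frequency falls
  continuously to ~16% of plateau — far below the Class II preset's
  ~75%, so the class ordering is preserved even though the strict <10%
  onset criterion is carried by the digital Class I preset.

One deliberate deviation surfaced during the square-wave derivation: the
acceptance-style check "the slow current rises during ≥90% of burst
*samples*" conflicts structurally with the square-wave geometry. The
relaxation cycle's return path necessarily lands on the left nullcline
branch below the rest point (the downstroke arrives at $n > n_{saddle}$),
so $f_q(v) < q$ for a crawl segment of every inter-spike interval and the
attainable instantaneous fraction caps near 0.55. An alternative
geometry that passes the instantaneous check (0.94/0.98) exits silence
through a Hopf rather than a saddle-node and shows no chaotic cascade —
it is not square-wave bursting. We ship the faithful square-wave preset;
the instantaneous burst-side check is implemented as stated and left
failing, while the silence-side check (≥90% of silent samples with
$dq/dt<0$) and the burst-averaged statement ($q$ rises over every burst,
falls over every silence) both hold and are asserted.

## The analysis toolkit

Equilibria are roots of a scalar condition in $v$ (all other states
slaved), bracketed on a dense grid, bisected, Newton-polished with the
analytic derivative, and classified by the eigenvalues of the analytic
Jacobian; every reported equilibrium carries a residual below $10^{-10}$
of the model's current scale. Bifurcation analysis is deliberately
sweep-and-detect rather than numerical continuation: each parameter
sample records the equilibrium structure and a simulated limit cycle
(transient = first half of the run discarded; a cycle is accepted when
the retained inter-spike intervals agree within 5%), and events are
classified from structural changes between adjacent samples. The cycle
search continues the previous sample's cycle state so that a coexisting
attractor inside a bistable window is not missed, falling back to a
fresh kick otherwise. f–I curves carry the state across intensities, so
up/down sweeps expose hysteresis; Class I onset grids must be refined
near threshold (the frequency falls off as a square root, which a
uniform grid undersamples) and `fi_curve(I_values=)` exists for exactly
that. Burst segmentation splits at gaps exceeding 3× the median
inter-spike interval — our convention, as no segmentation rule is
published.

`tune_mode()` is a seeded simulated annealer over a parameter box. Its
penalty encodes the published design heuristics: required equilibrium
counts and stabilities, an N-shaped v-nullcline, the
$\theta_v < \delta_m$ ordering (steep rising phase, shallower falling
phase), silence at rest with spiking under probe stimuli, and autonomous
burst/silence alternation for the square-wave target. A zero-penalty
candidate is re-verified with the classification machinery before the
report claims success; an exhausted budget returns a failure report with
the best candidate rather than an error.

## Synapses, learning, and the associative network

The kinetic synapse $dI_s/dt = \alpha(1-I_s)$ for $v \ge 0$ and
$-\beta I_s$ otherwise is integrated by forward Euler at the network
step and clipped to $[0,1]$; the accumulator computes
$I_{stim,j} = I_{ext,j} + c\sum_i W_{ji} I_{s,i}$. Correlation storage
is the bipolar outer product $W_{ij} = \tfrac1P\sum_u x_i^u x_j^u$
(zero diagonal; the canonical four-pattern divisor 4 generalizes to
$1/P$). The exponential STDP rule
$\Delta W = A_+e^{-|\Delta t|/\tau_+} - A_-e^{-|\Delta t|/\tau_-}$ is
applied over nearest-neighbour pairings — for each postsynaptic spike,
the signed time to the nearest presynaptic spike; the rule is even in
$\Delta t$, so the pairing-direction ambiguity is harmless.

The retrieval protocol: 256 digital neurons, all-to-all weights, common
375 µs step. Every neuron starts at the zero-stimulus rest state;
during a 20-step seed window only the neurons whose input-pattern pixel
is $+1$ are driven (they begin firing), then the sustained stimulus
reaches everyone. The seed window must come *before* the sustained
drive: applied on top of it, the phase split it creates is a few degrees
instead of the ~half-period needed to select a pattern. Spike phases
interpolate linearly between bracketing spikes; the overlap
$M_u = |\tfrac{1}{N'}\sum_j x_j^u e^{i\theta_j}|$ and synchronization
indices are circular order parameters over the $N'$ neurons with defined
phases. Because a balanced pattern state (two groups in anti-phase)
cancels the first-moment Kuramoto index to ~0, the metrics report both
`PSI` and the two-cluster parameter `PSI2`
$=|\tfrac{1}{N'}\sum e^{2i\theta_j}|$, which approaches 1 in exactly the
configurations a retrieved pattern produces. Success requires the
correct $M_u$ to hold above 0.8 for the final half of the run while
every other overlap stays below 0.5; retrieval of the reversed pattern
(sign structure inverted relative to the seeded group) is reported
separately and not counted.

The protocol constants ($\alpha=3000$, $\beta=400$, $c$, sustained
stimulus, seed length) were calibrated once per mode on the stored
presets and frozen: the Class II preset runs at $I_{ext}=0.7$ with
$c=0.012$, the Class I at $0.1$ with $c=0.02$. Two failure modes shaped
the calibration and are worth knowing about. A neuron inhibited into the
coexisting rest state of a Class II cell escapes only slowly (the focus
is weakly unstable), so a Class II preset with a narrow spiking band
suffers cascades of silenced neurons — the shipped preset's high
recovery-nullcline saturation is what prevents this. And STDP training
with the evolving weights fed back lets the first stored pattern capture
the dynamics and monopolize the weights; `stdp_training()` therefore
clamps by default (the accumulator is disabled during presentations, a
teacher-forcing choice), presenting each pattern and its reversal in
blocks of eight until the first weight saturates at $\pm 1$.

## What the synthetic patterns do and do not test

The stored patterns are seeded random ±1 vectors with pairwise overlap
capped at 0.25 — a stand-in for glyph patterns that exist only as
figures. Random patterns are the standard Hopfield setting and make the
four attractors statistically equivalent; structured glyphs correlate
more strongly and would lower the error tolerance. Passing retrieval
tests here demonstrates the mechanism (phase/activity pattern completion
over spiking dynamics with kinetic synapses), not performance on any
particular image set. Likewise the fixed seeds make every reported rate
a deterministic property of the shipped conditions; nearby seeds give
rates within the usual binomial spread of 10-trial experiments.

## Problem sizes and numerical choices

Fixed-step integrators only (classical RK4 at 10 µs default for the
analog models, forward Euler at 375 µs for the digital ones):
reproducibility and the fixed-point quantization contract rule out
adaptive stepping. Characterization runs in the tests use 1–25 s of
model time per condition; the bifurcation sweeps use 15–24 samples per
parameter range; the retrieval experiments use the full 256-neuron
network, 10 error levels × 10 trials per mode, 3 s per trial. The
divergence guard treats $|v| > 10$ V (analog) or $|v| > 100$ (digital)
as blow-up and names the time it happened. All randomness (pattern
draws, pixel flips, annealing proposals) flows through explicit integer
seeds; trial seeds derive deterministically from the base seed.

## Known limitations

* The ULP Class-I preset's onset is hysteretic rather than SNIC (see
  above); its onset-frequency ratio is ~0.16, not <0.1.
* The instantaneous burst-side $dq/dt$ fraction for square-wave bursting
  is structurally ≈0.5, documented above, and the corresponding check is
  expected to fail.
* STDP-trained weights saturate toward ±1, which discards the relative
  magnitudes that grade the correlation weights; the trained network
  retrieves at a lower rate (~0.5–0.7 at 10% error on pinned seed sets)
  than correlation storage in the Class I mode (~0.9). The training cadence and pairing scheme of the original
  hardware are unpublished, so our protocol is a documented stand-in.
* Event classification is bracketing-based; an event is localized only
  to one sweep interval, and degenerate double roots are not resolved.
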