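Package: qsn
Title: Qualitative-Modeling-Based Silicon Neuron Models and Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Software implementations of qualitative-modeling-based silicon
    neuron models: a three-variable analog membrane model built from
    differential-pair sigmoid and transconductance-amplifier tanh current
    curves, a two-variable ultralow-power subthreshold model, and a
    piecewise-quadratic digital spiking neuron solved by forward Euler in
    emulated fixed-point arithmetic. Includes a phase-plane and bifurcation
    toolkit (equilibria with stability, sweep-and-detect bifurcation
    diagrams, f-I curves and Hodgkin excitability classification, burst
    segmentation, period-doubling/chaos detection, and a seeded stochastic
    mode tuner), kinetic silicon synapses, exponential spike-timing-dependent
    plasticity, correlation learning, and an all-to-all spiking
    auto-associative memory with circular order-parameter retrieval metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
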