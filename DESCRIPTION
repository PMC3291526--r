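Package: stdpnet
Title: Two-Layer Network Simulations of Spike-Timing Dependent Plasticity at
    Top-Down Synapses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates learning at top-down (feedback) synapses in a two-layer
    model of reciprocally connected neocortical areas. Provides a linear
    firing-rate engine with an analytically tractable pairwise plasticity rule
    and a noisy conductance-based leaky integrate-and-fire engine with
    exponential-window spike-timing dependent plasticity (STDP), each in a
    classical and a temporally reversed (rSTDP) orientation with a tunable
    depression/potentiation bias. Includes homeostatic synaptic scaling,
    multiplicative (soft-bound) STDP, concurrent bottom-up plasticity and
    higher-layer external drive as rule variants, plus a parameter-sweep
    harness, four-way outcome classification (converged, extreme weights,
    weights too similar, did not converge), eigenvalue loop-gain diagnostics,
    and an input-reconstruction experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
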