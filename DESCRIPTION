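Package: memstdp
Title: Memristive Voltage-Based Synaptic Plasticity in Quadratic
    Integrate-and-Fire Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulator for a voltage-based spike-timing-dependent
    plasticity rule derived from memristive device dynamics: a bounded
    logistic weight update gated by pre-synaptic spikes and signed by the
    post-synaptic membrane potential, coupled to quadratic
    integrate-and-fire neurons in bidirectional all-to-all recurrent
    networks. Includes drivers for classical single-synapse plasticity
    protocols (voltage clamp, pairing windows, pair-frequency curves),
    rate- and temporally-coded pattern training of Hopfield-like
    auto-associative networks, pattern-completion metrics, and synthetic
    contour-image generation for scalable benchmarks.
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
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
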