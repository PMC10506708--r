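Package: stdpnet
Title: Motion Extrapolation by Spike-Timing Dependent Plasticity in
    Multi-Layer Feedforward Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a multi-layer feedforward network of Poisson-spiking,
    velocity-tuned neurons arranged on a circular stimulus space, in which
    spike-timing dependent plasticity (STDP) shifts feedforward receptive
    fields opposite to the direction of stimulus motion and thereby reduces
    the representational lag of moving stimuli. Provides the network and
    plasticity model (leaky rate integration with inter-layer transmission
    delays, balanced additive STDP with a growth ceiling and stochastic
    weight normalization), the spike-collection and flash-probe measurement
    protocols, and circular-statistics analysis tools (wrapped-Gaussian
    kernel density estimation, von Mises fitting, receptive-field shift and
    cross-layer alignment metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
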