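Package: epicosim
Title: Two-Scale Co-Simulation of Seizure Propagation: Epileptor Neural
    Fields Coupled to a Spiking CA1 Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for multiscale epilepsy simulation on cortical surface
    meshes. Implements the six-state spatial Epileptor neural-mass model
    with sparse delayed global coupling and Heaviside-gated local coupling
    over geodesic neighborhoods, a conductance-based spiking network of
    hippocampal CA1 with short-term synaptic plasticity, and a calibrated
    rate-to-Poisson conversion bridge that drives the spiking network from
    the field simulation in lockstep. Includes synthetic hippocampus
    geometry generation, vertex-to-neuron assignment with anatomical
    relabeling, network downscaling with integrity statistics, and
    phase-locking validation analyses (Hilbert phase, phase-locked spike
    histograms, vector strength, onset-latency maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    Rcpp,
    methods,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
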