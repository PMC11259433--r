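Package: myelinwm
Title: Multiscale Simulation of Myelin Dystrophy, Axonal Conduction, and
    Spatial Working Memory
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two linked models of how cortical myelin alterations affect
    cognition. A double-cable compartment model of a myelinated axon
    (nodes, paranodes, juxtaparanodes, internodes, tight junctions)
    quantifies conduction-velocity changes and action-potential failures
    under demyelination and remyelination of myelinated segments, across
    a Latin-hypercube cohort of axon morphologies, with lasso regression
    identifying the axon parameters that drive the responses. The
    per-neuron spike-transmission failure probabilities so obtained
    perturb a 20,000-neuron spiking ring-attractor network performing a
    spatial delayed response task; population-vector decoding yields
    memory strength, duration, drift, and diffusion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    glmnet,
    lhs,
    stats,
    ggplot2,
    jsonlite,
    withr,
    yaml,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
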