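Package: metaspike
Title: Simulators for Metabolically Regulated Neuronal Spiking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, seedable suite of models linking neuronal firing to
    mitochondrial energy homeostasis. Includes a reduced mitochondrial
    respiration model with reactive-oxygen-species (ROS) production, a
    threshold neuron that spikes to balance its metabolic budget, a
    Connor-Stevens-style neuron whose A-type potassium inactivation is
    switched by ROS, and a sparse recurrent conductance-based
    integrate-and-fire network in which a per-neuron metabolic current
    sustains activity after external input is removed. Ships avalanche
    detection and discrete power-law fitting for the resulting population
    activity, with tidy tabular outputs and ggplot2 helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
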