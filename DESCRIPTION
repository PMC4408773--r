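Package: larvatax
Title: Quantitative Analysis and Simulation of Larval Chemotaxis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of run-and-turn chemotaxis in
    Drosophila larvae from multi-animal tracking tables: Schmitt-trigger
    detection of turns and head casts, run segmentation, odor preference
    scores, bearing- and distance-resolved turn-rate and turning-direction
    statistics with circular sliding filters, and larval density maps. A
    two-state Markov agent-based simulator re-expresses the fitted
    behavioral policy (turn-rate lookup plus a bank of observed turning
    angles) as model larvae navigating a circular arena, with ablation
    modes that randomize turn rate and/or turning direction. A synthetic
    trajectory generator with closed-form ground truth closes the loop for
    validation and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
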