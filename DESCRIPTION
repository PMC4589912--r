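Package: immunobn
Title: Discrete Bayesian Network Analysis of Multi-Compartment Immune
    Mediator Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns discrete Bayesian networks from immune mediator panels
    measured in several body compartments of a two-hit (sepsis plus
    aspiration lung injury) murine study design.  Provides equal-frequency
    three-state discretization, Bayesian-Dirichlet (BDeu) network scoring,
    simulated-annealing structure search with an exhaustive enumerator as a
    small-problem oracle, consensus networks built from the top-scoring
    structures with a unanimity edge-orientation rule, detection of the
    collider ("V") and "Y" motifs used for causal interpretation, a
    calibrated synthetic cohort generator covering the full 12-group study
    design, and conventional group statistics (mean, SEM, t test, ANOVA with
    Tukey HSD) for side-by-side comparison with the network results.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
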