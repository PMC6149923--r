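Package: synergyabm
Title: Agent-Based Simulation and Loewe Synergy Prediction for Two-Drug
    Combinations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A 3D multiscale agent-based model of cancer-cell growth under
    two-drug exposure. Cells on a cubic lattice switch phenotype (apoptosis,
    proliferation, migration, quiescence) under stochastic rules driven by an
    exponential natural-mortality hazard and a linear dose-mortality term,
    while drug concentrations decay with their pharmacokinetic half-lives.
    Model parameters are calibrated against dose-inhibition tables in two
    stages: a gradient-descent least-squares fit of the dose-mortality
    coefficients, then a particle-swarm fit of the apoptosis mixing weights
    and hazard rate against simulated endpoint mortality. Calibrated models
    predict drug-combination synergy through the Loewe-additivity combination
    index at iso-effective doses. Includes a seeded synthetic dose-response
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    knitr,
    optparse,
    readr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
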