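Package: neurodyn
Title: Compartmental Dynamics of Adult Hippocampal Neurogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling adult hippocampal neurogenesis as a linear
    five-compartment system (neural stem cells, progenitors, neuroblasts,
    neurons, astrocytes) with explicit bookkeeping of symmetric and
    asymmetric divisions. Includes closed-form and numerical solutions of
    the cell-count dynamics, a bromodeoxyuridine (BrdU) pulse-chase
    labelling submodel, forward parameter-sensitivity analysis with
    sign-sequence classification of knockout responses, weighted
    nonlinear least-squares fitting of age-decline data, an exact
    stochastic (Gillespie) branching-process simulator used as an
    independent oracle, and a seeded synthetic-data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
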