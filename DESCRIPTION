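Package: adcstab
Title: Catalytic Stability and Kinetics of Mechanism-Based Enzyme Inactivation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for quantifying the catalytic (operational) stability of
    enzymes that undergo mechanism-based (suicide-substrate) inactivation,
    modelled on pyruvoyl-dependent L-aspartate-alpha-decarboxylase (ADC).
    Provides a Michaelis-Menten turnover model with turnover-coupled
    first-order loss of active enzyme and an ODE simulator; a progress-curve
    pipeline that fits a polynomial to product versus time, differentiates it
    to instantaneous activity, normalises to residual activity and fits a
    first-order decay to obtain half-life, inactivation rate and total
    turnover number; Michaelis-Menten parameter estimation by double-reciprocal
    and nonlinear least squares; Kyte-Doolittle hydropathy profiling of mutant
    protein sequences with a mutation-string parser; ranking of recombination
    candidates by predicted folding free-energy change; and seeded generators
    for synthetic progress curves, initial-rate tables and mock 96-well
    screening plates.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
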