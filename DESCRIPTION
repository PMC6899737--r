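Package: thermofr
Title: Temperature-Dependent Functional Responses and Consumer Energetics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fits temperature-dependent functional responses to prey-depletion
    feeding trials by maximum likelihood on a simulated depletion ODE, with
    Boltzmann-Arrhenius scaling of attack coefficients, handling times and
    natural mortality, and BIC selection over all parameter-sharing structures
    across experimental settings. Also fits mass- and temperature-scaling of
    routine metabolic rate from respirometry (with an optional quadratic
    temperature term and thermal-optimum extraction), and combines feeding and
    metabolic models into per-stream energetic efficiency of predator
    populations. Includes calibrated synthetic-data generators for feeding
    trials, respirometry records and stream surveys.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    mgcv,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
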