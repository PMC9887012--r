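Package: reefshield
Title: Coral Reef Structural Complexity and Coastal Wave Run-Up
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end probabilistic pipeline linking coral reef structural
    complexity to coastal wave run-up. Builds synthetic coral-populated reef
    cross-sections and measures their rumple-index structural complexity,
    converts complexity to Nikuradse hydraulic roughness profiles, propagates
    irregular waves across the reef with a one-dimensional Boussinesq model
    (surface-roller breaking, swash eddy viscosity, bed friction, dry-bed
    run-up), drives a copula-linked wave-climate ensemble, performs
    generalized Pareto extreme-value analysis of the 2 percent exceedance
    run-up, and fits a Bayesian interaction model of run-up on offshore wave
    height and structural complexity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite,
    rjags,
    coda
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
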