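Package: fluxsens
Title: Global Sensitivity Analysis of Nutrient Uptake in Constraint-Based
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Variance-based global sensitivity analysis of flux balance
    analysis (FBA) models. Perturbs the intake capacities (exchange-reaction
    lower bounds) of a constraint-based metabolic model over a common
    interval using a quasi-random Saltelli cross-sampling design, evaluates
    the optimal biomass objective for every parameterization with a built-in
    bounded-variable simplex solver, and estimates first-order and
    total-effect Sobol indices with bootstrap confidence intervals and
    factor rankings. Includes Morris elementary-effects screening and
    single-flux depletion analyses as comparators, a deterministic
    serial/parallel execution layer with checkpointing, readers for
    COBRA-style JSON and SBML (FBC) models, and toy model generators with
    analytically known sensitivities for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    parallel,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
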