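Package: larmex
Title: Exogenous Linear Autoregressive Mixed-Effects Models for Affect Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulation, estimation and parameter-recovery evaluation for
    day-level exogenous linear autoregressive mixed-effects (LARMEx) models of
    intraindividual affect networks measured by ecological momentary
    assessment. Provides a data-generating process with stability rejection
    sampling of day-level coefficients, construction of the stacked
    mixed-model design under missingness with listwise deletion, maximum
    likelihood and restricted maximum likelihood estimation of fixed effects
    and variance components with best linear unbiased prediction of day-level
    random effects, and a replication suite for bootstrap confidence
    intervals, relative estimation error, compliance and network-size
    comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    lme4,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
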