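Package: wildmeatr
Title: Hierarchical Bayesian Estimation of Household Wild Meat Consumption
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Joint Bayesian hierarchical analysis of household wild meat
    consumption surveys. Three linked submodels estimate the probability of
    consumption (Bernoulli), the frequency of consumption (Beta with
    monitoring-duration-dependent observation noise) and the daily quantity
    consumed per adult male equivalent (Gamma), with a latent Gaussian-process
    term for spatial autocorrelation between survey locations and Bayesian
    imputation of missing household composition. Includes standardization
    rules for recall-survey data, a synthetic-landscape generator for
    simulation-based calibration, posterior sampling with convergence
    diagnostics, and scenario-based grid prediction of consumption rates,
    consumed biomass, protein contribution and mapped uncertainty.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
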