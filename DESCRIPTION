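Package: poachval
Title: Tourism Losses and Anti-Poaching Returns for African Elephant
    Protected Areas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian errors-in-variables modelling of annual tourist
    visits to African protected areas as a log-linear function of latent
    elephant density and site covariates, with in-model imputation of
    missing population-count uncertainty.  Builds poaching
    counterfactuals by re-predicting visits at densities reduced by
    illegal killing, monetises the lost visits by Monte Carlo draws from
    fitted per-visit expenditure (exponential) and local-economy
    multiplier (truncated Gaussian) distributions, and assesses the
    spending shortfall and regional return on investment of stabilising
    large elephant populations.  Includes a synthetic-data generator
    that reproduces the statistical structure of the study design so the
    full pipeline is testable without the original survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
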