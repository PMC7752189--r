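Package: sdmnet
Title: Skills-Network Measurement of Shared Decision-Making Competence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models a physician's competence in shared decision making (SDM)
    as a directed, weighted network of nine behavioural skills rated by
    patients on the SDM-Q-9 questionnaire. Estimates one network per
    physician from nested consultation data using node-wise Bayesian
    multilevel regressions with random intercepts and slopes (via JAGS),
    selects between fixed- and random-effects models by DIC, purges edges
    whose credible intervals include zero, and derives per-physician node
    parameters (activation, outstrength, instrength). Scores observer-rated
    competence instruments (OPTION-12, OPTION-5, 4HCS 'Invest in the End')
    on a 0-100 scale with multilevel variance decomposition and inter-rater
    reliability, screens node parameters as predictors of observer-rated
    competence, fits final Bayesian prediction models, and predicts
    competence for new physicians from patient-reported data alone. A
    synthetic-data generator with known ground truth supports validation of
    every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    rjags,
    coda,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
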