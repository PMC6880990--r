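Package: phescreen
Title: Phenome-Disease Association Screening with Second-Generation
    P-Values and Literature Novelty Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens coded medical-record data for disease comorbidities.
    Visit-level ICD-9 codes are aggregated into phecodes, per-phecode
    logistic regressions estimate odds ratios against a case/control label
    with age and sex covariates, and findings are ranked two ways: by
    statistical reliability, using second-generation p-values against a
    pre-specified interval null plus an empirical-Bayes positive predictive
    value, and by literature novelty, using PubMed co-mention proportions
    turned into an empirical-CDF novelty score and a Novelty Finding Index.
    Includes age/sex-matched control selection with exclusion-code hygiene,
    three visit-censoring modes, three aggregate measures, a synthetic
    visit-level cohort generator with planted effects, and a pipeline driver
    with an odds-ratio plot.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
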