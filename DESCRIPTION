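Package: kcatboost
Title: Turnover-Number Prediction from Reaction Fingerprints and Enzyme
    Embeddings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A pipeline for predicting enzyme turnover numbers (kcat, in
    s^-1) for natural reactions of wild-type enzymes. Implements three
    numerical reaction fingerprints (structural, difference, and
    differential/symmetric-difference substructure fingerprints), a
    multi-source kinetic-data curation cascade with geometric-mean
    aggregation and plausibility filters, sequence-identity-aware
    train/test and cross-validation splitting, gradient-boosted tree
    regression with random-search hyperparameter optimization, a
    two-model prediction ensemble, and identity- and
    reaction-similarity-stratified evaluation. A seeded synthetic-data
    generator emulates the enzyme-family and reaction structure of
    curated kinetic databases so the full pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    Biostrings,
    xgboost,
    Matrix,
    digest,
    dplyr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
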