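Package: pcatree
Title: Decision-Tree Prediction of Patient-Controlled Analgesia Consumption
    and Readjustment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting postoperative patient-controlled analgesia
    (PCA) outcomes from tabular patient records: C4.5-style decision-tree
    induction with gain-ratio splits and pessimistic pruning, bagged and
    boosted tree ensembles, a nearest-neighbour "dirty example" cleaning
    method for class-imbalanced readjustment data, equal-deviation
    discretization of continuous dose targets, stratified repeated
    cross-validation with confusion-matrix metrics and paired significance
    tests, tree-based attribute-informativeness ranking with association
    tests and Monte-Carlo baselines, and a seeded synthetic cohort generator
    emulating the structure of hourly PCA usage records.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
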