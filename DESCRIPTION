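Package: cbccontam
Title: Retrospective Detection of IV Fluid Contamination in Complete Blood Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens longitudinal complete blood count (CBC) results for
    intravenous (IV) fluid contamination. Builds prior/current/post "CBC
    trios" from raw laboratory results, trains gradient-boosted tree
    classifiers on simulated linear-dilution contamination, calibrates a
    decision threshold to a target positive predictive value, estimates
    contamination severity (the mixture ratio) with a companion regressor,
    flags potentially unnecessary red-blood-cell transfusions with a
    three-criterion rule set, cross-checks predictions against paired basic
    metabolic panels, and explains predictions with exact tree-path Shapley
    attributions. Ships a seeded synthetic-cohort generator so the full
    pipeline runs without institutional data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    arrow,
    ggplot2,
    pROC,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
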