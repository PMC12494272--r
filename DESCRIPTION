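Package: heartgc
Title: Feature Importance and G-Computation for Binary Cardiac Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage analysis pipeline for tabular cardiac cohorts: consensus
    feature importance (information gain, shadow-feature random-forest selection,
    L1-penalised logistic regression) over thirteen clinical predictors, followed
    by g-computation (g-formula standardisation) of the average treatment effect
    of binarised treatments on heart-disease presence, with bootstrap inference
    and a raw/conditional/marginal odds-ratio decomposition. Includes a
    confounded synthetic-cohort generator with exactly computable causal truth,
    so every stage of the pipeline is testable without access to any study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
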