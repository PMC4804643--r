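Package: crtpredict
Title: Sequential Multi-Class Prediction of Chemoradiotherapy Response from Gene Expression
Version: 0.1.0
Authors@R:
    person("crtpredict", "developers", email = "crtpredict@example.org", role = c("aut", "cre"))
Description: Pipeline for predicting multi-class tumor regression (Dworak grade)
    after preoperative chemoradiotherapy from pre-treatment gene-expression
    profiles. Implements three per-gene feature scores combining Welch t-test
    p-values and effect sizes (p-value, rank product, normalized product),
    a bank of seven binary classifiers (linear SVM, random forest, elastic net,
    LDA, kNN with k = 1/3/5), 5-fold cross-validated grid model selection,
    a sequential TO-then-MI three-class decision rule, reference-based quantile
    normalization for cross-platform validation, and confusion-matrix
    evaluation with per-class sensitivities. Includes a seeded synthetic-cohort
    generator with planted differential expression so the full pipeline is
    testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    MASS,
    quadprog,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
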