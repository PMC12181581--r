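Package: opticog
Title: Optimized Cognitive Scoring and Classification for Cognitive Aging
    Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements an optimized cognitive scoring framework for
    longitudinal aging cohorts. A sign-constrained logistic scoring function
    maps six cognitive test channels (fluid intelligence, pairs-matching
    memory errors, reaction time at two visits) to a score in (0, 1); its
    parameters are tuned by a constrained adaptive-noise-scaling (CANS)
    derivative-free optimizer so that extreme-quantile class labels
    ("Positive-Ager" vs. "Cognitive Decliner") are maximally predictable from
    tabular white-matter diffusion MRI and demographic features. Includes the
    fast inner predictive pipeline (impurity-ranked feature selection plus
    L1-penalized logistic regression), a gradient-boosted final pipeline with
    sequential model-based hyperparameter search, PCA and single-block
    baselines, classification metrics and Hedge's g, Shapley-value feature
    importance with attribute/tract aggregation, a longitudinal trajectory
    calculus (adjusted scores, decision boundaries, slopes, integrated
    trajectory curves, first-visit prediction), and a synthetic cohort
    generator with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    lhs,
    MASS,
    ranger,
    rpart,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
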