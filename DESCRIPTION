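Package: rulefusion
Title: Fusing Diverse Decision Rules for Interpretable Diagnostic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts conjunctive decision rules from three tree-ensemble
    architectures (gradient boosting, random forest, AdaBoost), fuses them
    through a RuleFit-style sparse linear model, filters them by importance,
    outcome correlation and exact Shapley contributions, and fits an
    interpretable rule-based logistic model for binary diagnosis (invasive
    versus pre-invasive lung adenocarcinoma). Includes the two-phase
    radiomics feature-selection pipeline (variance filter, Spearman pruning,
    mRMR ranking, repeated LASSO stability selection), a textual rule
    dialect with parser and serializer, and synthetic-cohort generators so
    the whole workflow is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    randomForest,
    xgboost,
    rpart,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
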