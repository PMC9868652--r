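Package: strudem
Title: Structured Deep Embedding Models for Longitudinal Clinical Laboratory Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Hierarchy-constrained neural embedding models that compress
    irregular longitudinal laboratory measurements into small sets of
    interpretable composite indices for binary disease-risk prediction.
    Variables are bundled into redundancy groups ("combos") and further into
    clinically meaningful composite indices, and the network architecture is
    constrained so information flows only within these groups, yielding a
    readable one-dimensional embedding at every level of the hierarchy.
    Includes a seeded synthetic-cohort generator for irregularly sampled,
    highly missing lab records; cohort preparation (pre-diagnosis filtering,
    early-detection censoring, time-binned tensorization, propensity-score
    matching); repeated train/test evaluation with AUROC/AUPRC;
    cluster-purity entropy of the learned embeddings; per-layer Shapley
    attribution and four-classifier composite importance; and normal-range
    adjusted temporal trend statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    igraph,
    rpart,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mclust,
    ggplot2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
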