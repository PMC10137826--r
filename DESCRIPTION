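Package: mirpair
Title: Rank-Based miRNA-Pair Models for Cross-Platform COPD Diagnosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds platform-invariant diagnostic classifiers for chronic
    obstructive pulmonary disease (COPD) from circulating miRNA profiles.
    Expression matrices from heterogeneous platforms (microarray, RNA-seq,
    qPCR Ct values) are converted into binary miRNA-pair features that encode
    only the within-sample ordering of two miRNAs' abundances, making the
    feature space invariant to monotone platform distortions. Key pairs are
    selected by the consensus of four feature-selection algorithms (ROC
    filter, information gain, minimum-redundancy maximum-relevance, and a
    Boruta shadow-feature procedure), classifiers are tuned by grid search
    with stratified cross-validation, and single-patient predictions can be
    made from pair scores, raw expression, or Ct values. A two-platform
    synthetic cohort generator with planted rank-reversal pairs supports
    end-to-end testing and power experiments without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    pROC,
    purrr,
    randomForest,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
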