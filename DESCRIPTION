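Package: icbpairs
Title: Rank-Based Checkpoint Gene-Pair Features for Predicting Response to
    Immune Checkpoint Blockade
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building immune-checkpoint-blockade (ICB) response
    classifiers from bulk RNA-seq across multiple clinical studies. Expression
    matrices in counts, FPKM or TPM are harmonized to TPM, heterogeneous
    clinical response annotations are standardized to a binary outcome, and
    each sample is encoded as binary relative-expression indicators over
    anchor-constrained pairs of immune checkpoint genes. Because these
    pair features depend only on the within-sample ordering of expression
    values they are robust to study-specific batch distortions, which the
    package quantifies with hierarchical clustering purity and a
    nearest-neighbour batch-mixing score. Random forest, lasso-penalized
    logistic regression and gradient-boosted trees are evaluated under
    repeated stratified cross-validation with ROC/AUC summaries, per-feature
    selection probabilities and cross-method selection consistency. A
    multi-study synthetic data generator with planted class-dependent pair
    orderings makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
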