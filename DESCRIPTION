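Package: enhancerPRS
Title: Pretraining-Retraining Deep Learning for Tissue-Specific Enhancer
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts enhancer activity from DNA sequence with a hybrid
    convolutional and bidirectional gated-recurrent network, trained with a
    two-stage pretraining-retraining strategy: a model is first trained on a
    large pool of broadly active ("housekeeping") enhancers and then
    warm-start retrained for a small number of epochs on the few hundred
    enhancers available for an individual tissue or cell line. Includes the
    full dataset-construction pipeline (TPM-based positive selection from an
    enhancer activity matrix, length fixing, greedy redundancy reduction,
    intergenic negative sampling), imbalanced-classification evaluation
    (geometric mean, Matthews correlation, ROC and precision-recall areas),
    stratified cross-validation, hyperparameter grid search, and a synthetic
    motif-planting simulator so the whole pipeline can be exercised without
    external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
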