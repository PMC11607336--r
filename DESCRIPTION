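Package: notemia
Title: Membership-Inference Auditing of Clinical-Note Classifiers with
    Key-Phrase-Driven Synthetic Notes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end machinery for studying the privacy-utility
    trade-off of multilabel diagnosis-code classifiers trained on clinical
    free text.  Provides a seeded synthetic clinical-note corpus generator
    with code-conditional signature phrases and PHI surrogates, unsupervised
    key-phrase extraction (frequency-position and multi-feature scorers with
    fuzzy de-duplication), prompt construction and a deterministic offline
    note-generation backend, a bidirectional-LSTM label-attention ICD
    classifier, utility metrics (micro/macro AUC, precision, recall, F1,
    precision-at-k), and a shadow-model membership-inference attack suite
    (threshold, logistic, k-NN, random-forest and MLP attackers with
    balanced stratified two-fold scoring), plus orchestration for
    training-size, note-length and key-phrase-count sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    class,
    nnet,
    randomForest
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse
Config/testthat/edition: 3
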