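Package: snmda
Title: Sparse-Neighbourhood Prediction of miRNA-Disease Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate microRNA-disease associations from a sparse
    bipartite association network. Interaction profiles of miRNAs and diseases
    are re-expressed by L1-penalized sparse-neighbourhood reconstruction to
    yield learned similarity matrices, which are fused with precomputed miRNA
    functional similarity and DAG-based disease semantic similarity; candidate
    pairs are then scored by label propagation on both similarity networks.
    Includes the full cross-validation harness (global and local leave-one-out,
    repeated k-fold), ROC/AUC utilities, degree-distribution diagnostics, and
    synthetic network generators so the whole pipeline is testable without any
    external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
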