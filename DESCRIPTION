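Package: scmfpred
Title: miRNA-Disease Association Prediction by Matrix Decomposition and
    Similarity-Constrained Matrix Factorization
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts candidate miRNA-disease associations from a binary
    association matrix. The pipeline denoises the association matrix with a
    low-rank self-expression decomposition solved by inexact augmented
    Lagrange multipliers, fuses Gaussian interaction profile kernels with
    miRNA functional and disease semantic similarities through iterative
    similarity kernel fusion, and scores all pairs by a matrix factorization
    with L2 and graph-similarity penalties solved by exact per-row Newton
    updates. Includes DAG-based disease semantic similarity, fivefold and
    leave-one-out cross-validation protocols with rank-based AUC, and a
    seeded synthetic-data generator so the whole pipeline is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
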