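Package: cmlsig
Title: Single-Cell Cluster Signatures for Predicting Imatinib Response in
    Chronic Myeloid Leukemia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for peripheral-blood single-cell RNA-seq of
    chronic myeloid leukemia (CML). Provides quality-control filtering and
    log-normalization of UMI count matrices, PCA and graph-based clustering,
    Wilcoxon rank-sum marker detection with BH correction, module and
    cell-cycle scoring, projection of query cells onto a reference bone-marrow
    map via k-nearest-neighbor anchors in a shared PC space with kernel
    density rendering, a Pearson-correlation signature classifier that scores
    bulk pre-treatment expression cohorts against cluster signatures and
    evaluates prediction of imatinib non-response by ROC/AUC with DeLong
    confidence intervals, a permutation test for ligand-receptor interactions
    between clusters, and Fisher-exact enrichment of samples within clusters.
    A negative-binomial synthetic-data generator with planted ground truth
    supports end-to-end testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
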