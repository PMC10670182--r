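Package: scborda
Title: Batch Integration and Borda Consensus Feature Selection for
    Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale pipeline for multi-batch single-cell RNA-seq
    analysis: a negative-binomial simulator with planted marker genes and
    batch effects, standard QC/normalization and highly-variable-gene
    selection, CCA-based dataset integration with mutual-nearest-neighbor
    anchors and correction vectors, ensemble gene ranking (per-gene
    Wilcoxon rank-sum test and gradient-boosted-tree gain importance)
    fused by Borda rank aggregation, and evaluation of the selected gene
    set against planted ground truth including five-level regulation
    categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    xgboost,
    cluster,
    stats,
    utils,
    tools,
    methods,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pheatmap,
    withr
Config/testthat/edition: 3
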