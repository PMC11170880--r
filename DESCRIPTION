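Package: caracal
Title: Cell-Type Annotation for Single-Cell ATAC-Seq via Weighted
    Gene-Set Activity Scoring
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Annotates cell types in single-cell ATAC-seq data without a
    transcriptomic reference. Peak-level chromatin accessibility counts
    are projected to gene-level activity by summing peaks overlapping
    each gene body plus an upstream extension; per-cell-type weighted
    gene sets of up- and down-regulated genes are built from a labelled
    reference by one-vs-rest Wilcoxon rank-sum tests ranked on log2
    fold-change; each cell is scored per gene set with a
    variance-adjusted, origin-anchored Mahalanobis-type distance mapped
    through a gamma null to a [0,1] enrichment score; up and down scores
    are combined into a single cell-type score, cells are labelled by
    the top score, and ATAC-based scores can gate RNA-based scores by a
    per-type median threshold. Includes a negative-binomial simulator
    with planted marker programs for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    jsonlite,
    Matrix,
    methods,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    fitdistrplus,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
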