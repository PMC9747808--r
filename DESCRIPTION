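Package: culturedrift
Title: Tumor Versus Cell-Line Divergence Analysis for Multi-Omic Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for quantifying how tumor-derived cell lines diverge
    from primary tumors across bulk transcriptomes, micro-RNA profiles,
    protein quantifications and single-cell data. Implements resampled
    linear-SVM feature-stability selection with a two-pass immune blocklist,
    hypergeometric pathway over-representation with Benjamini-Hochberg FDR,
    lncRNA-miRNA-pathway (ceRNA sponge) network bridging with typed network
    export, empirical-Bayes location-scale batch correction of miRNA
    matrices with directional log-fold-change analysis, Mann-Whitney and
    Spearman concordance statistics, and a scaled-down single-cell stage
    (QC, graph clustering, marker typing, rank-sum markers, signature
    enrichment). A synthetic-cohort generator plants machine-readable ground
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    igraph,
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests:
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
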