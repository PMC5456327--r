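Package: fabrymeta
Title: Multi-Omics Literature Meta-Analysis of Fabry Disease Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Harmonises heterogeneous per-study differential-expression tables
    from Fabry disease literature into non-redundant consensus molecular
    features, and carries them through a complete meta-analysis: identifier
    alias resolution against a molecular cluster map, platform-specific and
    global fold-change/p-value thresholding, cross-study directionality
    consistency merging, functionality-tag composition summaries, gene-set
    over-representation with a two-sided hypergeometric test and Holm
    (Bonferroni step-down) correction, kappa-score term grouping,
    MAPPFinder-style pathway Z-scores, hierarchical clustering of fold-change
    profiles, shared-gene disease ranking, and miRNA/transcription-factor
    regulatory network overlays. A synthetic-data generator with planted
    ground truth makes every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    igraph,
    grDevices,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    pheatmap,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
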