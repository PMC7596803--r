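Package: lnenmap
Title: Molecular Maps of Lung Neuroendocrine Neoplasms with Embedding Quality Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and validates low-dimensional molecular maps of bulk
    RNA-seq cohorts, motivated by the pan-LNEN (lung neuroendocrine
    neoplasm) setting. From a gene-by-sample count matrix it computes a
    variance-stabilized expression matrix, selects the genes explaining a
    chosen fraction of total variance, and embeds samples with UMAP and
    PCA reference projections. Embedding quality is quantified with the
    rank-weighted sequence-difference (SD) neighborhood-preservation
    statistic scaled between PCA-5D and PCA-2D anchors, per-gene Moran-index
    spatial autocorrelation concordance against a hypergeometric null, and
    centroid-proximity Wilcoxon tests for molecular-subtype placement.
    Includes a negative-binomial synthetic-cohort generator with planted
    discordant samples, and writers for TumorMap-compatible layout and
    attribute files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    uwot,
    withr
Suggests:
    ape,
    DESeq2,
    jsonlite,
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
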