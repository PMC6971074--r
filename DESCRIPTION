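Package: mxifcell
Title: Single-Cell Immune Phenotyping for Multiplexed Immunofluorescence Tissue Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for high-dimensional single-cell
    analysis of immune infiltrates in cyclic multiplexed-immunofluorescence
    tissue images. Provides ground-truthed synthetic image generation, rigid
    DAPI-based round registration with autofluorescence subtraction,
    dual-mask segmentation (nuclear DAPI mask and combined leukocyte-lineage
    "targeted" mask), per-cell marker quantification, kNN/Jaccard/Louvain
    phenoclustering, rule-based nine cell-type classification of the
    inflammatory infiltrate, per-case T-cell exhaustion-state calling,
    permutation-based neighborhood enrichment and avoidance testing at short
    and long spatial range, and cohort-level clinical summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    Matrix,
    tiff,
    yaml,
    jsonlite,
    EBImage,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
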