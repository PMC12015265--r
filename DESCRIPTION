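Package: xenopool
Title: Pooled-Sample Variability Deconvolution for Xenobot Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing inter-individual gene-expression variability
    between groups profiled as pooled RNA-seq libraries. Implements the
    SE*sqrt(n) deconvolution of individual-level standard deviations from
    replicate pool values, coefficient-of-variation comparisons with a
    percentile bin-fraction permutation test, CPM filtering, TMM
    normalization and logCPM transforms, a stringent gene-list curation
    pipeline (cell-type set subtraction, LOC annotation, homeolog
    deduplication, ortholog mapping), gene-set overlap and phylostratum
    enrichment comparisons, and stimulus-response kinematics from tracking
    exports. A synthetic-data module generates every input with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    edgeR,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml,
    zoo
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
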