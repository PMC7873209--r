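Package: xaratio
Title: Chromosome-Element Expression Ratios and Sex-Chromosome Dosage in Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies sex-chromosome dosage compensation and meiotic
    sex-chromosome inactivation from single-cell and bulk RNA-seq of
    Drosophila testis. Provides per-cell chromosome-element expression
    ratios (X:A, 4:A) normalized by gene-set size, cell-label permutation
    inference built on the Mann-Whitney U test, data-driven housekeeping
    gene sets (Tau, TSPS, and a cell-level CTSP detection criterion),
    multiplet screening by clustering-stability grid search and in-silico
    mixing of cluster centroids, per-cell gene-set enrichment scores,
    bulk per-arm sex-bias statistics with bootstrap confidence intervals,
    and 3D chromosome-territory geometry (volume, surface area,
    sphericity, edge distances, background-subtracted intensity ratios).
    A fully parameterized synthetic-data generator reproduces the
    statistical structure of a larval testis atlas (ten cell types in
    germline and somatic lineages, per-element dosage regimes, doublets,
    and a multi-tissue two-sex bulk panel) so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    irlba,
    Matrix,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    mclust,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
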