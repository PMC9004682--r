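Package: methylfusion
Title: Multi-Omic Clustering, Validation and Fusion for Single-Cell
    Methylome, Transcriptome and Accessibility Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for joint analysis of single-nucleus DNA methylation,
    RNA expression and NOMe-seq chromatin accessibility profiled in the same
    cells. Implements bisulfite read partitioning into RNA and DNA bins by
    read-level non-CG methylation, beta-binomial posterior normalization of
    methylation rates with coverage-binned highly variable feature selection,
    binomial binarization of GpC accessibility with latent semantic analysis,
    Leiden consensus clustering with supervised reproducibility evaluation,
    cross-modal cluster validation (cross-validation error curves, AIC/BIC,
    over- and under-splitting scores built on CCA co-embedding and k-partners),
    cross-modality data fusion by restricted k-partners with feature
    imputation, and gene-level coupling analysis of gene-body mCH and RNA
    expression with an empirical shuffled null. Ships a seeded synthetic
    multi-modal data generator with known ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    irlba,
    RANN,
    ranger,
    generics,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    stats,
    utils,
    methods,
    withr
Suggests:
    uwot,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
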