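Package: bmsnn
Title: Biologically Meaningful Sparse Neural Networks for Multi-Task
    Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Ionome", "Prediction Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end genome-interpretation models for multi-task
    quantitative-trait prediction under dataset underdetermination.
    Provides a gene-centric encoding of annotated whole-genome variant
    tables (17 variant-type histograms per gene), a knowledge-sparsified
    neural trunk whose only trainable trunk weights follow a gene-to-pathway
    annotation map, two inductive transfer-learning schemes (frozen feature
    extractor and fine tuning), a GPS-coordinates-only baseline network, and
    a population-stratification-aware evaluation protocol: intra-country
    Pearson correlation, a replicate-based noise ceiling on attainable
    correlation, Simpson's-paradox diagnostics, and leakage-safe
    cross-validation planners.  A synthetic-data module generates
    country-structured genotype and phenotype tables so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
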