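Package: contextcore
Title: Context-Specific Metabolic Model Extraction from Discretized Expression
Version: 0.1.0
Authors@R: person("Context", "Core", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds flux-consistent, context-specific genome-scale metabolic
    models from discretized gene expression data. Implements flux consistency
    checking (FASTCC-style LP sweeps), FASTCORE-style context extraction with
    non-penalized transporter sets and forced biomass flux, Barcode-style
    z-score discretization, GPR Boolean rule evaluation, leave-one-out
    cross-validation of reaction confidence, flux variability and flux balance
    analysis, comparative model statistics (Jaccard clustering, pathway
    activity and regulation scores, gene essentiality with rank-based and
    hypergeometric validation), pathway entry-point classification with
    cofactor filtering, and an enhancer-load pipeline assigning reproducible
    ChIP peak regions to nearest genes to flag high-regulatory-load genes.
    Includes deterministic toy-model, expression and peak simulators so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    xml2,
    jsonlite,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
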