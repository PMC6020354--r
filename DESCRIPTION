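Package: ribobuffer
Title: Cross-Species Divergence and Buffering Analysis for Multi-Layer
    Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparing gene regulation across closely related
    species at three layers of the expression cascade: mRNA abundance
    (RNA-seq), ribosome occupancy (ribosome profiling), and steady-state
    protein level (SILAC-style log ratios). Implements detectability
    filtering, TMM/log2-RPKM normalisation with species-specific gene
    lengths, precision (voom) weights, parametric empirical-Bayes batch
    adjustment, moderated-t species-divergence tests, the
    interaction-model test for translation-efficiency divergence, the
    two-stage regression test for translational and post-translational
    buffering, ribosome-profiling quality metrics (codon periodicity at
    conserved initiation sites, k-mer footprint mappability), and
    downstream propagation, enrichment, and population-variance
    relaxation statistics. Ships a negative-binomial multi-omic
    simulator with known per-gene truth for benchmarking every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    limma,
    edgeR,
    Biostrings
Suggests:
    sva,
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
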