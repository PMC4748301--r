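Package: lincscan
Title: Identification and Characterization of Long Intergenic Noncoding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for discovering long intergenic
    noncoding RNAs (lincRNAs) from assembled transcript models and for
    characterizing their expression. Implements the classical identification
    cascade (length, intergenic position with gene flanks, hexamer-based
    coding-potential score, open reading frame length, housekeeping-RNA
    similarity, redundancy clustering), a seed-and-extend nucleotide homology
    search with Karlin-Altschul E-values for cross-species conservation,
    tissue-specificity (tau) and stage-specificity profiling, a weighted
    co-expression network (soft-threshold adjacency, topological overlap,
    module eigengenes, module-trait correlation, intramodular hubs), and
    hypergeometric GO-term enrichment with Bonferroni correction. Ships a
    synthetic-data generator that plants ground-truth lincRNA loci, decoys,
    tissue/stage-specific expression and trait-correlated co-expression
    modules, so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    SummarizedExperiment,
    rtracklayer,
    jsonlite,
    yaml,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
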