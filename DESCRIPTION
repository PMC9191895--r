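Package: pepfam
Title: Mining Secreted Peptide Families and Their Receptor Kinases from
    Proteomes and Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable comparative-genomics pipeline for discovering small
    secreted peptide-hormone families and delineating their cognate
    receptor-kinase clades across multiple plant species. Implements an
    expression-based screen for short secreted proteins, iterative
    profile search with empirically calibrated E-values, six-frame
    genomic rescue of unannotated family members, similarity-network
    community detection anchored on seed sequences, cysteine-spacing
    motif refinement, rule-based domain segmentation of receptor
    kinases, and neighbor-joining phylogenies with age-cutoff clade
    extraction. Ships a deterministic synthetic-data generator that
    plants ground-truth peptide and receptor families in simulated
    proteomes and genomes so every stage of the pipeline can be
    benchmarked end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    phytools,
    Biostrings,
    IRanges,
    S4Vectors,
    withr,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    igraph,
    optparse
Config/testthat/edition: 3
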