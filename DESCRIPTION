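Package: hibtarget
Title: Transcription-Factor Target-Gene Scanning and Phylogenetic
    Comparative Analysis of Hibernation-Associated Regulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Genome-scale analysis of transcription-factor target genes
    and binding affinity in relation to the mammalian hibernation trait.
    Builds log-odds position weight matrices from count matrices with
    exact score p-values computed by dynamic programming, scans genomes
    on both strands, calls target genes from motif hits in introns,
    exons and upstream promoter windows, and summarises per-species
    target ratios and binding-affinity scores.  Annotates ChIP peaks by
    genomic feature class and builds TSS-anchored regulatory windows.
    Fits codon substitution branch models (one-ratio, fixed omega = 1,
    free-ratio, two-ratio) by maximum likelihood with likelihood-ratio
    tests and per-branch substitution summaries, plus amino-acid
    conservation statistics.  Correlates a binary hibernation trait with
    genome-derived scores via Student's t-test, simulation-based
    phylogenetic ANOVA and a Bayesian threshold-model MCMC.  Seeded
    synthetic-data generators produce genomes with planted motif sites,
    ChIP-peak fixtures, codon alignments simulated under the branch
    model, and correlated traits on trees, each with a truth table.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    phytools,
    Matrix,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
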