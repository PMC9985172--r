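Package: bryostruct
Title: Genome Structure Evolution Statistics for Liverwort Comparative
    Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Comparative genome-structure statistics for haploid plant
    genomes, motivated by Marchantiopsida liverworts: duplicate-gene
    detection and the percent-duplicated statistic with a protein-length
    eligibility rule, collinear block chaining of single-copy ortholog
    anchors under minimum-block-size (s) and maximum-gap (m) parameters,
    transposable-element divergence landscapes with kernel-density burst
    detection and full-length LTR calling, and phylogenetic plus
    presence/absence classification of U/V sex-chromosome gametologs with
    U-to-autosome translocation inference.  A seeded genome-evolution
    simulator (inversions, translocations, duplications, losses, TE
    amplification bursts, gametolog histories) provides ground truth for
    every analysis.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
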