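Package: beescan
Title: Selection Scans and Ancestry Analysis for Admixed Honey-Bee Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying ancestry-mediated local adaptation in admixed
    (Africanized) honey-bee populations. Implements the full analysis chain
    used in elevation and latitude hybrid-zone studies: a seeded
    synthetic-data generator for admixed genomes (VCF, reference FASTA, GFF3,
    recombination map, local-ancestry posteriors, cline tables), a GATK-style
    variant filter cascade with haploid-drone handling, windowed nucleotide
    diversity and Weir-Cockerham FST, Reynolds genome-wide FST, KING-robust
    kinship, GC-content pericentromere detection by cumulative scoring,
    FST-quantile peak calling with exon-overlap gene annotation and
    hypergeometric enrichment, a two-deme coalescent null for divergence
    enrichment, and dependent-correlation comparison of ancestry clines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    stringr,
    jsonlite,
    stats,
    utils,
    Rcpp,
    vcfR,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
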