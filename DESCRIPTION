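Package: riffle
Title: MHC Amplicon Genotyping and Upstream-Downstream River Population Genetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genotyping major histocompatibility complex (MHC)
    class II beta exon 2 alleles from per-sample amplicon reads by
    hierarchical-clustering allele calling with duplicate-based
    repeatability estimation, and for the population-genetic analysis of
    the resulting allele tables in upstream versus downstream river
    populations. Includes a synthetic amplicon read simulator with a
    substitution plus homopolymer-indel error model, within-population
    diversity and equilibrium statistics (haplotype diversity, exact
    Hardy-Weinberg test by Markov chain and complete enumeration,
    Ewens-Watterson neutrality test), sequence-aware population structure
    (pairwise Phi-ST, hierarchical AMOVA, Dxy), codon-level selection
    inference (Nei-Gojobori dN/dS, codon Z-test, Hudson-Kaplan Rm,
    sliding-window scan), neighbor-joining allele trees, and a neutral
    microsatellite counterpart (GENEPOP parsing, Weir-Cockerham theta,
    rarefied allelic richness, Mantel isolation-by-distance tests).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
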