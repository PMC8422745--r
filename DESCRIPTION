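Package: coipopgen
Title: Single-Locus Mitochondrial Population Genetics from COI Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Complete single-locus mitochondrial DNA population-genetics
    workflow for aligned COI (or any mtDNA) sequences: haplotype collapsing
    and per-population frequency tables, molecular diversity indices
    (haplotype and nucleotide diversity with Nei sampling variances),
    Tajima's D and Fu's Fs neutrality tests with coalescent-simulation
    p-values, Rogers-Harpending mismatch-distribution fitting with
    sudden-expansion goodness-of-fit (SSD, raggedness) and mutational-clock
    expansion-time conversion, AMOVA/SAMOVA Phi-statistics with permutation
    tests, Kimura 2-parameter distances with UPGMA and neighbor-joining
    dendrograms, and statistical-parsimony (TCS-style) haplotype networks.
    Includes a haploid structured-coalescent simulator (island migration,
    sudden expansion, diverged demes, finite-sites mutation) used both for
    significance testing and for generating fully synthetic test data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    igraph,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
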