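Package: plastomics
Title: Comparative Plastome Analysis: SSR Composition, IR Junctions,
    Nucleotide Diversity and Diagnostic Markers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidy toolkit for comparative chloroplast-genome (plastome)
    analysis. Detects perfect simple sequence repeats (cpSSRs) with
    MISA-style unit-size thresholds and summarises their regional
    distribution over the quadripartite LSC/IRb/SSC/IRa frame; clusters
    species by cpSSR motif presence/absence (Sorensen dissimilarity,
    Ward.D2, Mantel permutation support) and scores motif informativeness;
    detects inverted-repeat boundaries from sequence and quantifies gene
    spans across IR/SC junctions; computes sliding-window and per-gene
    nucleotide diversity (Pi) with conservation categories; and types
    marker-gene alignments for SNPs (transition/transversion, A/T
    gain-loss), indels, diagnostic and private-allele sites, and pairwise
    identity. Seeded synthetic-data generators produce quadripartite
    plastomes and alignments with machine-readable truth sets for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
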