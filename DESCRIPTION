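Package: panvolve
Title: Pan-Genome Openness, Selection Pressure and Host-Microbe Interolog Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative pan-genomics toolkit for bacterial genome collections,
    motivated by probiotic and gut-commensal taxa. Builds gene families from
    protein sequences by greedy centroid clustering at an identity threshold,
    derives presence matrices and core/accessory/unique partitions, computes
    pan- and core-genome rarefaction curves with a Heaps-law openness
    classification, quantifies selection pressure via codon-usage
    Kullback-Leibler relative entropy (with Welch comparison of core versus
    chromosome) and Nei-Gojobori Ka/Ks on codon alignments, correlates
    functional-category and mobilome feature abundances with genome size,
    scans proteomes for conserved encrypted peptides, and predicts
    host-microbe protein-protein interactions by interolog transfer under
    joint homology filters. Includes a synthetic-genome generator with known
    ground truth (gene-family structure, tunable Heaps exponent, controlled
    omega and Ks, codon-usage bias) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
SystemRequirements: mafft (optional, for codon alignments of length-variable families)
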