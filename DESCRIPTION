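Package: ampedit
Title: CRISPR Edit Calling for Amplicon Sequencing of Multi-Copy Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects CRISPR/Cas9- and Cas12a-induced insertions and deletions,
    paired-guide excisions, and targeted double-stranded oligodeoxynucleotide
    (dsODN) replacements from merged amplicon reads mapped against a multi-reference
    panel of gene-family members, with wheat alpha-gliadins and their celiac-disease
    epitopes as the motivating use case. Provides dereplication and k-mer family
    screening, guide-site scanning under nuclease-specific PAM and seed rules,
    affine-gap local and semi-global alignment with indel normalization toward cut
    windows, abundance-weighted editing statistics, immunogenic epitope motif
    profiling, and a seeded simulator that generates reference panels and edited
    read sets with per-read truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
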