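Package: ampdiversity
Title: Amplicon Pyrosequencing Analysis of Antimicrobial Peptide Transcript Diversity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying transcript diversity of
    antimicrobial peptide (AMP) precursors from barcoded 454-style amplicon
    pyrosequencing. Covers barcode and fusion-primer design under homopolymer
    and pairwise-distance constraints, a 454-style read simulator with
    homopolymer-biased indel errors and per-read ground truth, barcode
    demultiplexing, modified-Mott quality trimming, semi-global mapping to
    reference amplicons, quality-aware pileups, genuine single-nucleotide-change
    (SNC) calling under coverage/frequency/quality filters, codon-aware
    synonymous/non-synonymous classification with the raw omega ratio, identical
    read clustering and non-redundant peptide-variant enumeration, and
    cross-sample variability statistics (one-way ANOVA with Tukey HSD
    homogeneous subsets).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
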