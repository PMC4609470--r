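Package: estpoly
Title: Comparative EST Polymorphism Analysis Between Transcript Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained pipeline for quantifying sequence polymorphism
    between two expressed-sequence-tag (EST) libraries: sequence cleaning,
    greedy overlap clustering into unigenes, filtered all-vs-all local
    alignment with best-hit selection, directional SNP and small/large indel
    calling, per-1000-nt frequency statistics, indel size and
    insertion/deletion-ratio spectra, flanking GC-content profiles, and
    mechanistic classification of large indels by boundary-repeat motifs.
    Includes a seeded divergence simulator that emits ground-truth variant
    tables so every stage can be validated offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
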