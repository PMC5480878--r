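Package: clonetrack
Title: Clonal IGH Amplicon Sequencing Analysis for Follicular Neoplasia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing clonal immunoglobulin heavy-chain (IGH)
    framework-2 amplicon sequencing of microdissected lymphoid follicles:
    demultiplexing, primer trimming, quality filtering, gap-aware mate merging,
    dereplication and noise filtering of short paired-end reads; V(D)J
    annotation against an annotated germline reference; discrimination of
    clone-specific reads against a monoclonal reference rearrangement and
    CDR3-defined subclone grouping; somatic-hypermutation statistics
    (replacement/silent ratios, substitution spectra, N-glycosylation sequon
    scanning); germline-rooted genealogies and interfollicular trafficking
    matrices. Includes a fully seeded synthetic-data generator that emulates
    microdissected-follicle amplicon runs with ground-truth labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
LinkingTo:
    Rcpp
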