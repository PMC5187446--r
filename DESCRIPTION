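Package: vgerm
Title: Individualized Germline V Gene Discovery from Antibody Repertoire
    Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers the individualized set of expressed germline
    immunoglobulin V alleles from an IgM (or light chain) amplicon
    sequencing library, starting from an arbitrary V database. Implements
    iterative assignment, percent-difference window clustering, UPGMA
    linkage clustering on Levenshtein distances, 60 percent majority
    consensus calling, and an evidence filter based on independent
    rearrangements (unique CDR3 junctions and J genes). Includes read
    preprocessing (pair merging, primer trimming, dereplication), upstream
    5'UTR/leader consensus detection, database comparison utilities, and a
    repertoire simulator with a per-read truth ledger.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
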