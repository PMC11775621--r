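Package: teloatac
Title: Telomere-Motif Read Quantification and Chromatin-Condensation Scoring for ATAC-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies telomere-like reads (tandem TTAGGG/CCCTAA motif runs,
    mostly of subtelomeric origin) in bulk and single-cell ATAC-seq libraries
    and summarises them as a normalized telomere abundance (nTA), a biomarker
    of chromatin condensation rather than of telomere length. Also provides
    reference-free reorientation and per-base motif matrices for telomere-like
    read pairs, detection of non-fragmenting Tn5 cargo insertions in long
    reads with target-site-duplication measurement, subtelomere boundary
    detection in nanopore telomere reads, a small convolutional regressor that
    infers the approximate genomic origin of 50-bp sequences, grouped
    correlation statistics between per-cell nTA and feature tables, and a
    synthetic-genome/read simulator so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    Biostrings,
    Rsamtools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
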