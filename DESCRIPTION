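Package: backsplicer
Title: In Silico Verification of Circular RNA Back-Splice Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembly-based verification of circular RNA (circRNA) back-splice
    junction candidates from aligned RNA-seq reads. Reads are extracted from a
    window on either side of a candidate junction, assembled into contigs with
    a built-in deterministic de Bruijn assembler, and aligned to a
    junction-spanning pseudo-reference; a candidate is verified when a single
    contig alignment covers the back-splice point with a minimum number of
    aligned bases on both sides, at four stringency levels (30/20/10/5 bp per
    side). Ships a paired-end circRNA read simulator with genome-placed SAM
    output and truth tables, and the evaluation arithmetic (sensitivity,
    precision, F1, spliced reads per billion mappings) needed to benchmark the
    pipeline end to end on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    IRanges,
    S4Vectors,
    tibble,
    dplyr,
    purrr,
    tidyr,
    stringr,
    stringi,
    readr,
    rlang,
    generics,
    ggplot2,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
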