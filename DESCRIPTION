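Package: tabooscan
Title: Exhaustive Alignment-Free Mining of k-Disjoint DNA Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds every length-W window of a query genome whose Hamming
    distance to every length-W window of a reference ("taboo") set exceeds k,
    without alignment or assembly. Words are integer-encoded in blocks of N
    letters (N-coding), block-level Hamming distances are precomputed in a
    mismatch matrix, and taboo windows (both strands) are partitioned into
    sub-lists addressed by their first two block codes, so a query only visits
    the sub-lists whose address-level distance can still permit a within-k
    match. Includes a synthetic-genome module with planted transition
    substitutions, inversions and insertions, and a naive letter-by-letter
    oracle used to verify the engine exhaustively. Applications include
    padlock-probe target design, CRISPR guide uniqueness pre-filtering, and
    detection of point mutations, inversions and viral incorporation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    withr,
    Biostrings,
    IRanges,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
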