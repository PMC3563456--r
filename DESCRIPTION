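Package: mirtronscreen
Title: Screening Small RNA-Seq Data for Mirtrons and Conserved Canonical miRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An absence-screening pipeline for microRNAs in a newly sequenced
    genome. Derives intron candidates from gene models, folds them into
    hairpins with a maximum-weight nested-pairing dynamic program, counts
    splice-site-anchored small RNA reads, and ranks candidate mirtrons three
    ways (structure, reads, combined). Screens for conserved canonical miRNAs
    by seed-match against known mature sequences and by genome identity-run
    scanning, and classifies candidate loci by their read-mapping signature
    (mature/star stacks, loop reads, 5'-end heterogeneity). Includes adapter
    trimming, read collapsing, a k-mer pigeonhole read mapper with an exact
    brute-force oracle, and a synthetic-data generator with a planted-truth
    ledger so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
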