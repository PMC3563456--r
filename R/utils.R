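#' @useDynLib mirtronscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rpois runif setNames plogis
#' @importFrom utils write.table read.delim
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of a DNA string
#'
#' Plain-character convenience wrapper around [Biostrings::reverseComplement()]
#' for the package's string-based internals.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' DNA to RNA and back
#'
#' @param x character vector.
#' @return character vector with T substituted by U (`dna_to_rna`) or U by T
#'   (`rna_to_dna`).
#' @export
dna_to_rna <- function(x) chartr("Tt", "Uu", x)

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Stable two-key ordering used for deterministic tie-breaks.
order_by_locus <- function(df) order(df$seq_id, df$start, df$end, df$strand)
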