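#' Adapter-trimming and read-filtering parameters
#'
#' Defaults reflect standard small-RNA practice for 3'-adapter libraries:
#' a minimum adapter overlap of 5 nt with at most a 10% mismatch fraction,
#' and a post-trim filter keeping 18–26 nt reads (the mature-miRNA length
#' spectrum) with mean Phred quality of at least 20 and no N. Qualities are
#' Phred+33.
#'
#' @param adapter 3' adapter sequence (DNA).
#' @param min_overlap minimum read-suffix/adapter-prefix overlap in nt.
#' @param max_mismatch_fraction maximum mismatch fraction over the overlap.
#' @param min_len,max_len kept read-length window after trimming, in nt.
#' @param min_mean_quality minimum mean Phred score.
#' @return a list of class `trim_params`.
#' @export
trim_params <- function(adapter = "ATCTCGTATGCCGTCTTCTGCTTGT",
                        min_overlap = 5L, max_mismatch_fraction = 0.1,
                        min_len = 18L, max_len = 26L,
                        min_mean_quality = 20) {
  stopifnot(min_overlap > 0, min_overlap <= nchar(adapter),
            max_mismatch_fraction >= 0, max_mismatch_fraction <= 1)
  structure(list(adapter = toupper(adapter), min_overlap = as.integer(min_overlap),
                 max_mismatch_fraction = max_mismatch_fraction,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 min_mean_quality = min_mean_quality),
            class = "trim_params")
}

#' Read a FASTQ file of raw small-RNA reads
#'
#' Quality strings are kept verbatim and interpreted as Phred+33 downstream;
#' a quality character below '!' or above 'J' (typical Phred+64 territory)
#' is rejected with an error rather than silently mis-scored.
#'
#' @param fastq_path path to an uncompressed or gzipped FASTQ file.
#' @return data.frame with `read_id`, `sequence`, `qualities`, `count` (1).
#' @export
read_fastq_reads <- function(fastq_path) {
  stopifnot(file.exists(fastq_path))
  set <- Biostrings::readDNAStringSet(fastq_path, format = "fastq",
                                      with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(set)$qualities)
  if (length(quals) > 0) {
    rng <- range(utf8ToInt(paste(quals, collapse = "")))
    if (rng[1] < 33 || rng[2] > 74) {
      stop("quality encoding does not look like Phred+33 (char range ",
           rng[1], "-", rng[2], ")")
    }
  }
  data.frame(read_id = sub("\\s.*$", "", names(set)),
             sequence = as.character(set), qualities = quals,
             count = rep(1L, length(set)), stringsAsFactors = FALSE)
}

#' Trim the 3' adapter from raw reads
#'
#' Scans each read for the leftmost position where a suffix of the read
#' matches a prefix of the adapter with overlap of at least `min_overlap` nt
#' and mismatch fraction at most `max_mismatch_fraction`; a full internal
#' adapter occurrence is the special case of a complete-prefix overlap. The
#' read (and its quality string) is truncated before that position. Reads
#' with no admissible overlap pass through unchanged — they are dealt with by
#' the length filter.
#'
#' @param reads data.frame from [read_fastq_reads()].
#' @param params a [trim_params()] object.
#' @return the data.frame with trimmed `sequence`/`qualities`.
#' @export
trim_adapter <- function(reads, params = trim_params()) {
  if (nrow(reads) == 0) return(reads)
  stopifnot(all(nchar(reads$sequence) > 0))
  pos <- trim_positions(reads$sequence, params$adapter, params$min_overlap,
                        params$max_mismatch_fraction)
  hit <- pos > 0L
  reads$sequence[hit] <- substr(reads$sequence[hit], 1L, pos[hit] - 1L)
  if (!is.null(reads$qualities)) {
    reads$qualities[hit] <- substr(reads$qualities[hit], 1L, pos[hit] - 1L)
  }
  reads
}

mean_phred <- function(qual_strings) {
  vapply(qual_strings, function(q) {
    if (nchar(q) == 0) return(NA_real_)
    mean(utf8ToInt(q) - 33)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Length, quality and N filter for trimmed reads
#'
#' Keeps reads whose trimmed length lies in `[min_len, max_len]`, whose mean
#' Phred+33 quality is at least `min_mean_quality`, and which contain no N.
#' Reads without quality strings (e.g. simulated or already-collapsed input)
#' are exempt from the quality criterion only.
#'
#' @inheritParams trim_adapter
#' @return the filtered data.frame.
#' @export
quality_length_filter <- function(reads, params = trim_params()) {
  if (nrow(reads) == 0) return(reads)
  len <- nchar(reads$sequence)
  keep <- len >= params$min_len & len <= params$max_len &
    !grepl("N", reads$sequence, fixed = TRUE)
  if (!is.null(reads$qualities)) {
    mq <- mean_phred(reads$qualities)
    keep <- keep & (is.na(mq) | mq >= params$min_mean_quality)
  }
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse reads to unique sequences with multiplicities
#'
#' One record per distinct sequence; `count` sums the input multiplicities,
#' so the total read count is conserved. Output order is by descending count
#' then lexicographic sequence, and ids are rewritten `seq<rank>_x<count>`
#' (miRDeep-style).
#'
#' @param reads data.frame with `sequence` and `count` columns.
#' @return collapsed data.frame with `read_id`, `sequence`, `count`.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0) {
    return(data.frame(read_id = character(), sequence = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  counts <- tapply(reads$count, reads$sequence, sum)
  out <- data.frame(sequence = names(counts),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  out <- data.frame(read_id = sprintf("seq%d_x%d", seq_len(nrow(out)), out$count),
                    sequence = out$sequence, count = out$count,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write collapsed reads as FASTA (counts in headers) and TSV
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param fasta_path,tsv_path output paths; either may be `NULL` to skip.
#' @return invisibly, the paths written.
#' @export
write_collapsed <- function(collapsed, fasta_path = NULL, tsv_path = NULL) {
  if (!is.null(fasta_path)) {
    set <- Biostrings::DNAStringSet(setNames(collapsed$sequence,
                                             collapsed$read_id))
    Biostrings::writeXStringSet(set, fasta_path)
  }
  if (!is.null(tsv_path)) {
    write.table(collapsed[c("sequence", "count")], tsv_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(c(fasta_path, tsv_path))
}

#' Remove reads matching a contaminant blocklist
#'
#' Optional subtraction of known contaminants (e.g. an over-represented rRNA
#' fragment pool) supplied as a FASTA of sequences: a read is removed when it
#' occurs as an exact substring of any blocklist sequence, on either strand.
#'
#' @param reads collapsed or raw read data.frame.
#' @param blocklist_fasta path to a FASTA of contaminant sequences, or `NULL`.
#' @return the read data.frame with contaminant reads removed.
#' @export
subtract_blocklist <- function(reads, blocklist_fasta = NULL) {
  if (is.null(blocklist_fasta) || nrow(reads) == 0) return(reads)
  block <- read_genome(blocklist_fasta)
  hay <- paste(c(block, revcomp(block)), collapse = "#")
  keep <- !vapply(reads$sequence, grepl, logical(1), x = hay, fixed = TRUE,
                  USE.NAMES = FALSE)
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
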