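#' Build a k-mer index over a genome
#'
#' Indexes every forward-strand k-mer position; k-mers containing N are
#' skipped. Reverse-strand hits are found at query time by mapping the
#' reverse complement of the read. The pigeonhole principle guarantees full
#' sensitivity for a read of length L with m mismatches when
#' `floor(L / k) >= m + 1`; shorter reads fall back to an exhaustive scan in
#' [map_read()].
#'
#' @param genome named character vector from [read_genome()].
#' @param k seed length in nt (6–8 in practice; at least 2).
#' @return an object of class `mapper_index`.
#' @export
build_index <- function(genome, k = 8L) {
  stopifnot(k >= 2)
  if (any(nchar(genome) < k)) {
    stop("k = ", k, " exceeds the length of the shortest sequence")
  }
  lookup <- lapply(genome, function(s) {
    n <- nchar(s) - k + 1L
    starts <- seq_len(n)
    kmers <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    list2env(split(starts[ok], kmers[ok]), envir = new.env(parent = emptyenv()))
  })
  structure(list(k = as.integer(k), lookup = lookup,
                 seq_ids = names(genome), seq_len = nchar(genome)),
            class = "mapper_index")
}

empty_alignments <- function() {
  data.frame(read = character(), seq_id = character(), start = integer(),
             end = integer(), strand = character(), mismatches = integer(),
             stringsAsFactors = FALSE)
}

# Seed-and-verify on the forward genome for one oriented read sequence.
seed_hits_one_strand <- function(read, index, genome, max_mismatches) {
  k <- index$k
  m <- nchar(read)
  n_seeds <- m %/% k
  offs <- (seq_len(n_seeds) - 1L) * k
  seeds <- substring(read, offs + 1L, offs + k)
  out <- list()
  for (sid in index$seq_ids) {
    env <- index$lookup[[sid]]
    starts <- integer(0)
    for (t in seq_len(n_seeds)) {
      pos <- env[[seeds[t]]]
      if (!is.null(pos)) starts <- c(starts, pos - offs[t])
    }
    starts <- unique(starts)
    starts <- starts[starts >= 1L & starts + m - 1L <= index$seq_len[[sid]]]
    if (!length(starts)) next
    starts <- sort(starts)
    mm <- hamming_at(genome[[sid]], read, starts)
    keep <- mm <= max_mismatches
    if (any(keep)) {
      out[[length(out) + 1L]] <- data.frame(seq_id = sid,
                                            start = starts[keep],
                                            mismatches = mm[keep],
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Exhaustive one-strand scan (fallback when the pigeonhole condition fails).
scan_hits_one_strand <- function(read, genome, max_mismatches) {
  out <- list()
  for (sid in names(genome)) {
    hits <- scan_positions(genome[[sid]], read, max_mismatches)
    if (nrow(hits)) {
      out[[length(out) + 1L]] <- data.frame(seq_id = sid,
                                            start = hits[, 1],
                                            mismatches = hits[, 2],
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Map one read to the genome with up to a fixed number of mismatches
#'
#' Substitution-only (no indels) mapping on both strands, reporting every
#' alignment within the mismatch budget — equal-best and suboptimal alike,
#' since splice-site signatures need multi-mapped reads. Uses k-mer
#' pigeonhole seeding with Hamming verification; reads too short for the
#' pigeonhole guarantee at the requested budget are scanned exhaustively so
#' completeness always holds (verified against [brute_force_map()]).
#'
#' @param read read sequence (DNA, as sequenced).
#' @param index a [build_index()] object over `genome`.
#' @param genome the same named character vector the index was built from.
#' @param max_mismatches maximum substitutions (default 2).
#' @return data.frame of alignments `read`, `seq_id`, `start`, `end` (1-based
#'   inclusive), `strand`, `mismatches`, ordered by (seq_id, start, strand);
#'   a read that maps nowhere gives zero rows.
#' @export
map_read <- function(read, index, genome, max_mismatches = 2L) {
  read <- toupper(rna_to_dna(read))
  map_read_core(read, revcomp(read), index, genome, max_mismatches)
}

map_read_core <- function(read, read_rc, index, genome, max_mismatches) {
  pigeonhole_ok <- (nchar(read) %/% index$k) >= (max_mismatches + 1L)
  one <- if (pigeonhole_ok) {
    function(r) seed_hits_one_strand(r, index, genome, max_mismatches)
  } else {
    function(r) scan_hits_one_strand(r, genome, max_mismatches)
  }
  fwd <- one(read)
  rev <- one(read_rc)
  rows <- list()
  if (!is.null(fwd)) { fwd$strand <- "+"; rows <- c(rows, list(fwd)) }
  if (!is.null(rev)) { rev$strand <- "-"; rows <- c(rows, list(rev)) }
  if (!length(rows)) return(empty_alignments())
  out <- do.call(rbind, rows)
  out$read <- read
  out$end <- out$start + nchar(read) - 1L
  out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out[c("read", "seq_id", "start", "end", "strand", "mismatches")]
}

#' Brute-force exhaustive mapping oracle
#'
#' Position-by-position Hamming comparison on both strands, delegated to
#' [Biostrings::matchPattern()] with `with.indels = FALSE` and `fixed = TRUE`
#' (so N in the genome never matches) — an implementation independent of the
#' seeded mapper, used to certify its completeness.
#'
#' @inheritParams map_read
#' @return data.frame in the same layout as [map_read()].
#' @export
brute_force_map <- function(read, genome, max_mismatches = 2L) {
  read <- toupper(rna_to_dna(read))
  rows <- list()
  for (sid in names(genome)) {
    subj <- Biostrings::DNAString(genome[[sid]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else revcomp(read)
      if (nchar(pat) > length(subj)) next
      hits <- Biostrings::matchPattern(pat, subj,
                                       max.mismatch = max_mismatches,
                                       with.indels = FALSE, fixed = TRUE)
      if (length(hits) == 0) next
      mm <- Biostrings::neditStartingAt(pat, subj,
                                        starting.at = Biostrings::start(hits),
                                        with.indels = FALSE, fixed = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        read = read, seq_id = sid, start = Biostrings::start(hits),
        end = Biostrings::end(hits), strand = strand, mismatches = mm,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_alignments())
  out <- do.call(rbind, rows)
  out <- out[order(out$seq_id, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a table of collapsed reads
#'
#' Runs [map_read()] for each collapsed read and annotates alignments with
#' the collapsed multiplicity (`read_count`) and the read's total number of
#' alignments (`n_hits`, for unique-mapper tallies). Multi-mapped reads are
#' not fractionally weighted: every alignment carries the full count.
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @inheritParams map_read
#' @return alignment data.frame with extra columns `read_id`, `read_count`,
#'   `n_hits`.
#' @export
map_reads <- function(collapsed, index, genome, max_mismatches = 2L) {
  seqs <- toupper(rna_to_dna(collapsed$sequence))
  rcs <- if (nrow(collapsed)) revcomp(seqs) else character(0)
  res <- lapply(seq_len(nrow(collapsed)), function(i) {
    aln <- map_read_core(seqs[i], rcs[i], index, genome, max_mismatches)
    if (nrow(aln) == 0) return(NULL)
    aln$read_id <- collapsed$read_id[i]
    aln$read_count <- collapsed$count[i]
    aln$n_hits <- nrow(aln)
    aln
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    out <- empty_alignments()
    out$read_id <- character()
    out$read_count <- integer()
    out$n_hits <- integer()
    return(out)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write alignments as a TSV (and optionally BED6)
#'
#' @param alignments data.frame from [map_reads()].
#' @param tsv_path output TSV; `bed_path` optional BED6 (score = mismatches).
#' @return invisibly, the paths written.
#' @export
write_alignments <- function(alignments, tsv_path, bed_path = NULL) {
  write.table(alignments, tsv_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(bed_path)) {
    df <- alignments
    df$name <- if (!is.null(df$read_id)) df$read_id else df$read
    df$score <- df$mismatches
    write_bed6(df, bed_path)
  }
  invisible(c(tsv_path, bed_path))
}
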