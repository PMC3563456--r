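#' Read a genome FASTA into a named character vector
#'
#' Residues are uppercased and U is converted to T, so downstream code works
#' on a single DNA alphabet. Duplicated sequence identifiers and non-IUPAC
#' residues are hard errors; only A/C/G/T/N are accepted after normalisation
#' (ambiguity codes other than N are not supported by the mapper or folder).
#'
#' @param fasta_path path to a FASTA file.
#' @return named character vector of uppercase DNA sequences; names are the
#'   first whitespace-delimited token of each header.
#' @export
read_genome <- function(fasta_path) {
  stopifnot(file.exists(fasta_path))
  set <- Biostrings::readBStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id(s) in ", fasta_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- chartr("Uu", "Tt", toupper(as.character(set)))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-IUPAC residue in record(s): ", paste(ids[bad], collapse = ", "))
  }
  setNames(seqs, ids)
}

#' Read exon records from a GFF3 file
#'
#' Keeps `exon` features and groups them by their `Parent` attribute (the
#' transcript). Exons with several parents (shared between isoforms) are
#' duplicated, one row per parent, as intron derivation works per transcript.
#'
#' @param gff_path path to a GFF3 file with exon features carrying Parent.
#' @return data.frame with columns `seq_id`, `start`, `end`, `strand`,
#'   `transcript_id` (1-based inclusive coordinates).
#' @export
read_exons <- function(gff_path) {
  stopifnot(file.exists(gff_path))
  gr <- rtracklayer::import(gff_path, format = "gff3")
  gr <- gr[tolower(as.character(gr$type)) == "exon"]
  if (length(gr) == 0) {
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      transcript_id = character()))
  }
  parents <- gr$Parent
  n_par <- lengths(parents)
  if (any(n_par == 0)) stop("exon feature without a Parent attribute")
  idx <- rep(seq_along(gr), n_par)
  data.frame(
    seq_id = as.character(GenomicRanges::seqnames(gr))[idx],
    start = GenomicRanges::start(gr)[idx],
    end = GenomicRanges::end(gr)[idx],
    strand = as.character(GenomicRanges::strand(gr))[idx],
    transcript_id = unlist(parents, use.names = FALSE),
    stringsAsFactors = FALSE
  )
}

#' Derive intron candidates from exon records
#'
#' Exons are grouped by transcript and sorted by genomic coordinate; every
#' gap between adjacent exons becomes one intron. Introns shared between
#' isoforms are collapsed on (seq_id, start, end, strand). The donor is the
#' intron terminus adjacent to the transcript-upstream exon (genomic start on
#' '+', genomic end on '-').
#'
#' @param exons data.frame as returned by [read_exons()].
#' @return data.frame of introns: `seq_id`, `start`, `end`, `strand`,
#'   `length`, `donor_pos`, `acceptor_pos` (no sequence yet; see
#'   [attach_sequence()]).
#' @export
derive_introns <- function(exons) {
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      length = integer(), donor_pos = integer(),
                      acceptor_pos = integer(), stringsAsFactors = FALSE)
  if (nrow(exons) == 0) return(empty)
  stopifnot(all(exons$start <= exons$end))
  pieces <- lapply(split(exons, exons$transcript_id), function(tx) {
    tx <- tx[order(tx$start), , drop = FALSE]
    if (nrow(tx) > 1 && any(tx$start[-1] <= tx$end[-nrow(tx)])) {
      stop("overlapping exons in transcript ", tx$transcript_id[1])
    }
    if (nrow(tx) < 2) return(NULL)
    gs <- tx$end[-nrow(tx)] + 1L
    ge <- tx$start[-1] - 1L
    keep <- gs <= ge  # zero-gap adjacency emits no intron
    if (!any(keep)) return(NULL)
    data.frame(seq_id = tx$seq_id[1], start = gs[keep], end = ge[keep],
               strand = tx$strand[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- out[!duplicated(out[c("seq_id", "start", "end", "strand")]), ,
             drop = FALSE]
  out <- out[order_by_locus(out), , drop = FALSE]
  out$length <- out$end - out$start + 1L
  out$donor_pos <- ifelse(out$strand == "+", out$start, out$end)
  out$acceptor_pos <- ifelse(out$strand == "+", out$end, out$start)
  rownames(out) <- NULL
  out
}

#' Attach the spliced-intron RNA sequence to intron candidates
#'
#' The sequence is the genomic slice on '+' and the reverse complement on
#' '-', written as RNA (T to U) in transcript 5'-to-3' orientation — the
#' orientation in which a mirtron hairpin would fold after splicing.
#'
#' @param introns data.frame from [derive_introns()].
#' @param genome named character vector from [read_genome()].
#' @return the input data.frame with a `sequence` column (RNA alphabet).
#' @export
attach_sequence <- function(introns, genome) {
  if (nrow(introns) == 0) {
    introns$sequence <- character(0)
    return(introns)
  }
  if (!all(introns$seq_id %in% names(genome))) {
    stop("intron on unknown sequence: ",
         paste(setdiff(introns$seq_id, names(genome)), collapse = ", "))
  }
  lens <- nchar(genome)[introns$seq_id]
  if (any(introns$start < 1L | introns$end > lens)) {
    stop("intron interval out of sequence bounds")
  }
  slice <- substring(genome[introns$seq_id], introns$start, introns$end)
  minus <- introns$strand == "-"
  if (any(minus)) slice[minus] <- revcomp(slice[minus])
  introns$sequence <- dna_to_rna(unname(slice))
  introns
}

#' Filter introns by length window
#'
#' Bounds are inclusive on both ends, so the core window `[50, 120]` and the
#' extension window `[121, 150]` are disjoint.
#'
#' @param introns intron data.frame with a `length` column.
#' @param min_len,max_len window bounds in nt.
#' @return the filtered data.frame.
#' @export
filter_by_length <- function(introns, min_len, max_len) {
  stopifnot(min_len <= max_len)
  introns[introns$length >= min_len & introns$length <= max_len, ,
          drop = FALSE]
}

#' Write intervals as BED6
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention. The name field defaults to
#' `seq_id:start-end(strand)` in 1-based inclusive style.
#'
#' @param df data.frame with `seq_id`, `start`, `end`, `strand` and
#'   optionally `name` and `score` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(df, path) {
  name <- if (!is.null(df$name)) df$name else
    sprintf("%s:%d-%d(%s)", df$seq_id, df$start, df$end, df$strand)
  score <- if (!is.null(df$score)) df$score else rep(0L, nrow(df))
  bed <- data.frame(df$seq_id, df$start - 1L, df$end, name, score, df$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
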