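# Shared fixture builders. Everything is generated in code; no binary files.

write_fasta_tmp <- function(seqs) {
  path <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(names(seqs), function(n) c(paste0(">", n),
                                                      seqs[[n]]))), path)
  path
}

write_fastq_tmp <- function(ids, seqs, quals = NULL) {
  if (is.null(quals)) {
    quals <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  }
  path <- tempfile(fileext = ".fastq")
  writeLines(as.vector(rbind(paste0("@", ids), seqs, "+", quals)), path)
  path
}

# random DNA string
rdna <- function(n, letters = c("A", "C", "G", "T")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

exon_df <- function(seq_id, starts, ends, strand = "+", tx = "tx1") {
  data.frame(seq_id = seq_id, start = starts, end = ends, strand = strand,
             transcript_id = tx, stringsAsFactors = FALSE)
}

# Reference adapter-trim scan, independent of the C++ implementation:
# leftmost position whose read-suffix / adapter-prefix overlap of length
# >= min_overlap has mismatch fraction <= max_mm.
trim_pos_oracle <- function(read, adapter, min_overlap, max_mm) {
  alen <- nchar(adapter)
  for (p in seq_len(nchar(read))) {
    ov <- min(alen, nchar(read) - p + 1L)
    if (ov < min_overlap) break
    a <- substr(read, p, p + ov - 1L)
    b <- substr(adapter, 1L, ov)
    mm <- sum(utf8ToInt(a) != utf8ToInt(b))
    if (mm <= floor(max_mm * ov)) return(p)
  }
  0L
}

# One full-scale simulated study per seed, computed lazily and cached so the
# recovery and classification acceptance checks share the work.
.study_cache <- new.env(parent = emptyenv())

study_run <- function(seed) {
  key <- as.character(seed)
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  dir <- file.path(tempdir(), sprintf("study_seed%d", seed))
  cfg <- sim_config(seed = seed)
  bundle <- generate_two_samples(cfg, out_dir = dir)
  rc <- run_config(genome_fasta = file.path(dir, "genome.fa"),
                   gff = file.path(dir, "annotation.gff3"),
                   fastqs = file.path(dir, c("sample1.fastq",
                                             "sample2.fastq")),
                   out_dir = file.path(dir, "out"))
  res <- suppressMessages(run_pipeline(rc))
  out <- list(truth = bundle$sim$truth, res = res,
              emitted1 = attr(bundle$reads1, "locus_read_counts"),
              emitted2 = attr(bundle$reads2, "locus_read_counts"))
  .study_cache[[key]] <- out
  out
}

# classification of planted loci of one kind: TRUE when any overlapping
# classified locus is plausible
planted_plausible <- function(truth, loci, kind) {
  tt <- truth[truth$kind == kind, , drop = FALSE]
  tg <- GenomicRanges::GRanges(tt$seq_id, IRanges::IRanges(tt$start, tt$end),
                               strand = tt$strand)
  lg <- GenomicRanges::GRanges(loci$seq_id,
                               IRanges::IRanges(loci$start, loci$end),
                               strand = loci$strand)
  ov <- GenomicRanges::findOverlaps(tg, lg)
  hit <- rep(NA, nrow(tt))  # NA: locus not recovered at all
  for (q in unique(S4Vectors::queryHits(ov))) {
    cls <- loci$classification[S4Vectors::subjectHits(ov)[
      S4Vectors::queryHits(ov) == q]]
    hit[q] <- any(cls == "plausible")
  }
  hit
}
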