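test_that("read_genome normalises case and RNA letters", {
  path <- write_fasta_tmp(list(s = "acgu"))
  g <- read_genome(path)
  expect_identical(g, c(s = "ACGT"))
})

test_that("read_genome rejects duplicate ids and bad residues", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGGG"), path)
  expect_error(read_genome(path), "duplicate")
  path2 <- write_fasta_tmp(list(ok = "ACGT", bad = "ACXT"))
  expect_error(read_genome(path2), "bad")
})

test_that("read_genome on an empty file gives an empty set", {
  path <- tempfile(fileext = ".fa")
  file.create(path)
  expect_length(read_genome(path), 0)
})

test_that("derive_introns computes gaps between adjacent exons", {
  ex <- exon_df("s", c(1, 151), c(100, 200))
  introns <- derive_introns(ex)
  expect_equal(nrow(introns), 1)
  expect_equal(introns$start, 101)
  expect_equal(introns$end, 150)
  expect_equal(introns$length, 50)
  expect_equal(introns$donor_pos, 101)
  expect_equal(introns$acceptor_pos, 150)
})

test_that("donor and acceptor swap on the minus strand", {
  ex <- exon_df("s", c(1, 151), c(100, 200), strand = "-")
  introns <- derive_introns(ex)
  expect_equal(introns$donor_pos, 150)
  expect_equal(introns$acceptor_pos, 101)
})

test_that("single-exon transcripts and zero gaps yield no introns", {
  expect_equal(nrow(derive_introns(exon_df("s", 1, 100))), 0)
  # adjacent exons with no gap
  expect_equal(nrow(derive_introns(exon_df("s", c(1, 101), c(100, 200)))), 0)
})

test_that("isoform-shared introns collapse to one record", {
  ex <- rbind(exon_df("s", c(1, 151), c(100, 200), tx = "tx1"),
              exon_df("s", c(1, 151), c(100, 250), tx = "tx2"))
  expect_equal(nrow(derive_introns(ex)), 1)
})

test_that("overlapping exons within a transcript are a hard error", {
  ex <- exon_df("s", c(1, 50), c(100, 200))
  expect_error(derive_introns(ex), "overlapping")
})

test_that("derive_introns is invariant to exon input order", {
  ex <- exon_df("s", c(1, 151, 301), c(100, 200, 400))
  shuffled <- ex[c(3, 1, 2), ]
  expect_equal(derive_introns(ex), derive_introns(shuffled))
})

test_that("exon and intron lengths add up to the transcript span", {
  set.seed(42)
  for (rep in 1:20) {
    n_ex <- sample(2:6, 1)
    lens <- sample(50:200, n_ex)
    gaps <- sample(0:150, n_ex - 1)
    starts <- integer(n_ex); ends <- integer(n_ex)
    pos <- sample(1:100, 1)
    for (e in seq_len(n_ex)) {
      starts[e] <- pos
      ends[e] <- pos + lens[e] - 1L
      if (e < n_ex) pos <- ends[e] + gaps[e] + 1L
    }
    ex <- exon_df("s", starts, ends)
    introns <- derive_introns(ex)
    expect_equal(sum(lens) + sum(introns$length),
                 max(ends) - min(starts) + 1L)
  }
})

test_that("attach_sequence returns transcript-oriented RNA", {
  g <- c(s = "AAACCTAAA")
  plus <- data.frame(seq_id = "s", start = 4, end = 7, strand = "+",
                     length = 4)
  minus <- plus; minus$strand <- "-"
  expect_equal(attach_sequence(plus, g)$sequence, "CCUA")
  # reverse complement of genomic ACCT, written as RNA
  minus$start <- 3; minus$end <- 6
  expect_equal(attach_sequence(minus, g)$sequence, "AGGU")
})

test_that("attach_sequence rejects out-of-bounds intervals", {
  g <- c(s = "ACGT")
  bad <- data.frame(seq_id = "s", start = 2, end = 9, strand = "+")
  expect_error(attach_sequence(bad, g), "bounds")
})

test_that("reverse complement is an involution", {
  set.seed(7)
  seqs <- vapply(1:10, function(i) rdna(sample(10:80, 1)), character(1))
  expect_identical(revcomp(revcomp(seqs)), seqs)
})

test_that("length filter bounds are inclusive and windows disjoint", {
  introns <- data.frame(seq_id = "s", start = 1, end = c(49, 50, 120, 121),
                        strand = "+", length = c(49, 50, 120, 121))
  core <- filter_by_length(introns, 50, 120)
  expect_setequal(core$length, c(50, 120))
  ext <- filter_by_length(introns, 121, 150)
  expect_setequal(ext$length, 121)
  expect_equal(nrow(filter_by_length(introns[0, ], 50, 120)), 0)
})

test_that("GFF3 written by the generator round-trips through read_exons", {
  cfg <- sim_config(n_genes = 4, n_planted_mirtrons = 1,
                    n_planted_canonical = 0, n_scatter_decoys = 0,
                    n_decoy_structured_introns = 0, n_scaffolds = 2,
                    background_read_count = 0, seed = 5)
  dir <- tempfile()
  sim <- generate_genome(cfg, out_dir = dir)
  ex <- read_exons(file.path(dir, "annotation.gff3"))
  got <- ex[order(ex$transcript_id, ex$start),
            c("seq_id", "start", "end", "strand", "transcript_id")]
  want <- sim$exons[order(sim$exons$transcript_id, sim$exons$start),
                    c("seq_id", "start", "end", "strand", "transcript_id")]
  rownames(got) <- rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("BED6 export converts to 0-based half-open", {
  df <- data.frame(seq_id = "s", start = 101, end = 150, strand = "+")
  path <- tempfile(fileext = ".bed")
  write_bed6(df, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(bed$V2, 100)
  expect_equal(bed$V3, 150)
  expect_equal(bed$V4, "s:101-150(+)")
})
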