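small_cfg <- function(seed = 1, ...) {
  sim_config(n_genes = 12, n_planted_mirtrons = 2, n_planted_canonical = 2,
             n_scatter_decoys = 1, n_decoy_structured_introns = 1,
             n_scaffolds = 2, background_read_count = 150, seed = seed, ...)
}

test_that("identical seeds give byte-identical outputs", {
  d1 <- tempfile(); d2 <- tempfile()
  generate_two_samples(small_cfg(seed = 101), out_dir = d1)
  generate_two_samples(small_cfg(seed = 101), out_dir = d2)
  for (f in c("genome.fa", "annotation.gff3", "truth.tsv", "sample1.fastq",
              "sample2.fastq")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
})

test_that("different seeds change the genome", {
  s1 <- generate_genome(small_cfg(seed = 103))
  s2 <- generate_genome(small_cfg(seed = 104))
  expect_false(identical(s1$genome, s2$genome))
})

test_that("a config with no planted loci yields a pure-decoy ledger", {
  cfg <- sim_config(n_genes = 8, n_planted_mirtrons = 0,
                    n_planted_canonical = 0, n_scatter_decoys = 0,
                    n_decoy_structured_introns = 0, n_scaffolds = 1,
                    background_read_count = 50, seed = 107)
  sim <- generate_genome(cfg)
  expect_false(any(sim$truth$kind %in% c("mirtron", "canonical", "scatter")))
})

test_that("infeasible configs are rejected", {
  expect_error(sim_config(n_genes = 2, exons_per_gene = 2,
                          n_planted_mirtrons = 10), "infeasible")
})

test_that("planted truth intervals lie inside the genome with arms at the
           splice sites", {
  sim <- generate_genome(small_cfg(seed = 109))
  tr <- sim$truth
  expect_true(all(tr$start >= 1))
  expect_true(all(tr$end <= nchar(sim$genome)[tr$seq_id]))
  mt <- tr[tr$kind == "mirtron", ]
  for (r in seq_len(nrow(mt))) {
    row <- mt[r, ]
    donor <- if (row$strand == "+") row$start else row$end
    acceptor <- if (row$strand == "+") row$end else row$start
    m5 <- if (row$strand == "+") row$mature_start else row$mature_end
    s3 <- if (row$strand == "+") row$star_end else row$star_start
    expect_equal(m5, donor)     # mature arm abuts the donor
    expect_equal(s3, acceptor)  # star arm ends at the acceptor
  }
})

test_that("raw reads are fixed-length, adapter-bearing and Phred+33", {
  sim <- generate_genome(small_cfg(seed = 113))
  reads <- simulate_reads(sim, 1L)
  expect_true(all(nchar(reads$sequence) == 36))
  expect_true(all(nchar(reads$qualities) == 36))
  # most reads carry a recognisable adapter prefix after the insert
  has_adapter <- grepl(substr(sim$config$adapter, 1, 8), reads$sequence,
                       fixed = TRUE)
  expect_gt(mean(has_adapter), 0.8)
})

test_that("unexpressed loci emit no reads and counts are ledgered", {
  sim <- generate_genome(small_cfg(seed = 127))
  reads <- simulate_reads(sim, 1L)
  em <- attr(reads, "locus_read_counts")
  tr <- sim$truth
  decoy <- tr$locus_id[tr$kind == "decoy_hairpin"]
  expect_true(all(em$n_mature[em$locus_id %in% decoy] == 0))
  expressed <- tr$locus_id[tr$kind %in% c("mirtron", "canonical")]
  # Poisson(20) mass below 5 or above 40 is ~1e-4; with a handful of loci
  # all counts should fall well inside
  expect_true(all(em$n_mature[em$locus_id %in% expressed] >= 5))
  expect_true(all(em$n_mature[em$locus_id %in% expressed] <= 45))
})

test_that("simulated mature reads map back onto the planted arm", {
  sim <- generate_genome(small_cfg(seed = 131))
  reads <- simulate_reads(sim, 1L)
  collapsed <- collapse_reads(quality_length_filter(trim_adapter(reads)))
  idx <- build_index(sim$genome, 6)
  aln <- map_reads(collapsed, idx, sim$genome)
  tr <- sim$truth[sim$truth$kind == "mirtron", ][1, ]
  intron <- data.frame(seq_id = tr$seq_id, start = tr$start, end = tr$end,
                       strand = tr$strand,
                       donor_pos = ifelse(tr$strand == "+", tr$start, tr$end),
                       acceptor_pos = ifelse(tr$strand == "+", tr$end,
                                             tr$start))
  sig <- count_splice_reads(intron, aln)
  em <- attr(reads, "locus_read_counts")
  n_emitted <- em$n_mature[em$locus_id == tr$locus_id]
  expect_gte(sig$n5, round(0.7 * n_emitted))
})

test_that("sample-specific loci express in exactly one sample", {
  cfg <- small_cfg(seed = 137, sample_specific_fraction = 1)
  bundle <- generate_two_samples(cfg)
  tr <- bundle$sim$truth
  expressed <- tr$kind %in% c("mirtron", "canonical", "scatter")
  expect_true(all(tr$specificity[expressed] %in% c("s1", "s2")))
  e1 <- attr(bundle$reads1, "locus_read_counts")
  e2 <- attr(bundle$reads2, "locus_read_counts")
  tot1 <- rowSums(e1[, -1]); tot2 <- rowSums(e2[, -1])
  only1 <- tr$specificity == "s1" & expressed
  only2 <- tr$specificity == "s2" & expressed
  expect_true(all(tot1[only2] == 0))
  expect_true(all(tot2[only1] == 0))
  expect_true(any(tot1[only1] > 0))
  expect_true(any(tot2[only2] > 0))
})
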