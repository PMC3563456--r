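feat <- function(stem = 0L, loop = 0L, pf = 0, oh5 = 0L, oh3 = 0L,
                 bulges = 0L) {
  structure(list(stem_len = stem, loop_len = loop, paired_fraction = pf,
                 overhang5 = oh5, overhang3 = oh3, n_bulges = bulges,
                 gu_fraction = 0), class = "hairpin_features")
}

test_that("structure score has the designed floor and ceiling", {
  # pairless 100-nt intron: overhangs split the whole length
  expect_lt(score_mirtron_structure(feat(oh5 = 50L, oh3 = 50L)), 0.05)
  # textbook pre-miRNA-like hairpin
  good <- feat(stem = 30L, loop = 6L, pf = 60 / 68, oh3 = 2L)
  expect_gt(score_mirtron_structure(good), 0.9)
})

test_that("structure score is monotone in stem length and pairing", {
  base <- feat(stem = 10L, loop = 6L, pf = 0.5)
  expect_lt(score_mirtron_structure(base),
            score_mirtron_structure(feat(stem = 20L, loop = 6L, pf = 0.5)))
  expect_lt(score_mirtron_structure(base),
            score_mirtron_structure(feat(stem = 10L, loop = 6L, pf = 0.8)))
})

test_that("bulges, bad loops and long overhangs are penalised", {
  clean <- feat(stem = 20L, loop = 8L, pf = 0.8)
  expect_gt(score_mirtron_structure(clean),
            score_mirtron_structure(feat(stem = 20L, loop = 8L, pf = 0.8,
                                         bulges = 3L)))
  expect_gt(score_mirtron_structure(clean),
            score_mirtron_structure(feat(stem = 20L, loop = 30L, pf = 0.8)))
  expect_gt(score_mirtron_structure(clean),
            score_mirtron_structure(feat(stem = 20L, loop = 8L, pf = 0.8,
                                         oh5 = 12L)))
})

intron_row <- function(strand = "+", start = 101L, end = 192L) {
  data.frame(seq_id = "s", start = start, end = end, strand = strand,
             length = end - start + 1L,
             donor_pos = ifelse(strand == "+", start, end),
             acceptor_pos = ifelse(strand == "+", end, start),
             stringsAsFactors = FALSE)
}

aln_row <- function(start, end, strand = "+", count = 1L, n_hits = 1L) {
  data.frame(read = "x", seq_id = "s", start = start, end = end,
             strand = strand, mismatches = 0L, read_id = "r",
             read_count = count, n_hits = n_hits, stringsAsFactors = FALSE)
}

test_that("splice-anchored counting follows orientation and buffer", {
  intron <- intron_row("+")
  # 5' end exactly at the donor
  sig <- count_splice_reads(intron, aln_row(101, 122), buffer = 3)
  expect_equal(sig$n5, 1)
  expect_equal(sig$n3, 0)
  # antisense read at the same position does not count
  sig2 <- count_splice_reads(intron, aln_row(101, 122, strand = "-"))
  expect_equal(sig2$total, 0)
  # buffer edges: +3 counts, +4 does not
  expect_equal(count_splice_reads(intron, aln_row(104, 125))$n5, 1)
  expect_equal(count_splice_reads(intron, aln_row(105, 126))$n5, 0)
  # 3' end at the acceptor counts for the 3' site
  expect_equal(count_splice_reads(intron, aln_row(171, 192))$n3, 1)
  # no alignments at all
  expect_equal(count_splice_reads(intron, aln_row(500, 520))$total, 0)
})

test_that("minus-strand introns anchor at their transcript termini", {
  intron <- intron_row("-")
  # on '-', the read 5' end is its rightmost base; donor is intron end
  sig <- count_splice_reads(intron, aln_row(171, 192, strand = "-"))
  expect_equal(sig$n5, 1)
  sig3 <- count_splice_reads(intron, aln_row(101, 122, strand = "-"))
  expect_equal(sig3$n3, 1)
})

test_that("counts sum collapsed multiplicities and split unique mappers", {
  intron <- intron_row("+")
  aln <- rbind(aln_row(101, 122, count = 6L, n_hits = 1L),
               aln_row(102, 123, count = 4L, n_hits = 3L))
  sig <- count_splice_reads(intron, aln)
  expect_equal(sig$n5, 10)
  expect_equal(sig$unique5, 6)
  expect_equal(sig$distinct5, 2)
})

test_that("a read spanning both splice sites counts once per site", {
  intron <- intron_row("+", 101L, 122L)  # 22-nt intron
  sig <- count_splice_reads(intron, aln_row(101, 122))
  expect_equal(sig$n5, 1)
  expect_equal(sig$n3, 1)
  expect_equal(sig$total, 2)
})

test_that("rankings are permutations with deterministic tie-breaks", {
  cand <- data.frame(seq_id = "s", start = c(10, 50), end = c(100, 140),
                     strand = "+", length = 91,
                     structure_score = c(0.9, 0.5),
                     splice_total = c(0, 10), stringsAsFactors = FALSE)
  rk <- rank_candidates(cand)
  expect_equal(rk$rank_structure, c(1, 2))
  expect_equal(rk$rank_reads, c(2, 1))
  # combined sums tie at 3; coordinate breaks the tie
  expect_equal(rk$rank_combined, c(1, 2))
  one <- rank_candidates(cand[1, ])
  expect_equal(one$rank_structure, 1)
  expect_equal(one$rank_combined, 1)
})

test_that("each ranking is a permutation of 1..N on simulated candidates", {
  set.seed(29)
  cfg <- sim_config(n_genes = 30, n_planted_mirtrons = 3,
                    n_planted_canonical = 0, n_scatter_decoys = 0,
                    n_decoy_structured_introns = 3,
                    background_read_count = 100, seed = 29)
  sim <- generate_genome(cfg)
  introns <- attach_sequence(derive_introns(sim$exons), sim$genome)
  reads <- simulate_reads(sim, 1L)
  collapsed <- collapse_reads(quality_length_filter(trim_adapter(reads)))
  idx <- build_index(sim$genome, 6)
  aln <- map_reads(collapsed, idx, sim$genome)
  ranked <- mirtron_screen(introns, aln)
  for (col in c("rank_structure", "rank_reads", "rank_combined")) {
    expect_setequal(ranked[[col]], seq_len(nrow(ranked)))
  }
  # splice totals never exceed the local alignment mass
  for (i in sample(nrow(ranked), 10)) {
    near <- aln[aln$seq_id == ranked$seq_id[i] &
                  aln$start <= ranked$end[i] + 3 &
                  aln$end >= ranked$start[i] - 3, ]
    expect_lte(ranked$splice_total[i], 2 * sum(near$read_count))
  }
})

test_that("the extension window is screened separately", {
  set.seed(37)
  cfg <- sim_config(n_genes = 20, n_planted_mirtrons = 2,
                    n_extended_mirtrons = 2, n_planted_canonical = 0,
                    n_scatter_decoys = 0, n_decoy_structured_introns = 0,
                    background_read_count = 0, seed = 37)
  sim <- generate_genome(cfg)
  introns <- attach_sequence(derive_introns(sim$exons), sim$genome)
  reads <- simulate_reads(sim, 1L)
  collapsed <- collapse_reads(quality_length_filter(trim_adapter(reads)))
  idx <- build_index(sim$genome, 6)
  aln <- map_reads(collapsed, idx, sim$genome)
  core <- mirtron_screen(introns, aln)
  ext <- extended_length_screen(introns, aln)
  tr <- sim$truth
  ext_truth <- tr[tr$kind == "mirtron" & tr$extended, ]
  key <- function(df) paste(df$seq_id, df$start, df$end)
  expect_true(all(key(ext_truth) %in% key(ext)))
  expect_false(any(key(ext_truth) %in% key(core)))
  expect_true(all(core$length >= 50 & core$length <= 120))
  expect_true(all(ext$length >= 121 & ext$length <= 150))
})
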