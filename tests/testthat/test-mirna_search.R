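MIR100 <- "ACCCGUAGAUCCGAACUUGUG"
MIR2022 <- "UUUGCUAGUUGCUUUUGUCCC"

test_that("the seed is positions 2-7 of the mature sequence", {
  expect_equal(seed_of(MIR100), "CCCGUA")
  expect_equal(seed_of(MIR2022), "UUGCUA")
  expect_error(seed_of("ACGUAC"), "seed")
})

mutate_at <- function(seq, positions) {
  for (p in positions) {
    substr(seq, p, p) <- setdiff(c("A", "C", "G", "U"), substr(seq, p, p))[1]
  }
  seq
}

test_that("matching requires an identical seed and <=3 mismatches elsewhere", {
  known <- list(name = "mir-x", sequence = paste0(MIR100, "A"))  # 22 nt
  expect_s3_class(match_mature(known$sequence, known), "seed_match")
  expect_equal(match_mature(known$sequence, known)$mismatches_rest, 0)
  # one mismatch inside the seed kills the match
  expect_null(match_mature(mutate_at(known$sequence, 4), known))
  # three mismatches outside the seed are tolerated, four are not
  expect_s3_class(match_mature(mutate_at(known$sequence, c(9, 14, 20)), known),
                  "seed_match")
  expect_null(match_mature(mutate_at(known$sequence, c(9, 14, 18, 20)), known))
})

test_that("the seed/arm rule holds on an exhaustive mismatch-placement grid", {
  known <- list(name = "mir-x", sequence = paste0(MIR100, "A"))
  seed_pos <- 2:7
  rest_pos <- setdiff(1:22, seed_pos)
  set.seed(41)
  for (n_seed in 0:2) {
    for (n_rest in 0:5) {
      for (rep in 1:4) {
        cand <- mutate_at(known$sequence,
                          c(sample(seed_pos, n_seed),
                            sample(rest_pos, n_rest)))
        hit <- match_mature(cand, known)
        if (n_seed == 0 && n_rest <= 3) {
          expect_s3_class(hit, "seed_match")
          expect_equal(hit$mismatches_rest, n_rest)
        } else {
          expect_null(hit)
        }
      }
    }
  }
})

test_that("match decisions are symmetric at equal lengths", {
  set.seed(43)
  for (rep in 1:20) {
    a <- rdna(22, c("A", "C", "G", "U"))
    b <- mutate_at(a, sample(1:22, sample(0:5, 1)))
    ab <- match_mature(a, list(name = "b", sequence = b))
    ba <- match_mature(b, list(name = "a", sequence = a))
    expect_equal(is.null(ab), is.null(ba))
  }
})

test_that("length reconciliation compares over the shorter sequence", {
  known <- list(name = "mir-x", sequence = MIR100)  # 21 nt
  cand <- paste0(MIR100, "GGG")  # 24 nt: overhang uncounted
  expect_s3_class(match_mature(cand, known), "seed_match")
})

test_that("a verbatim genomic copy gives a full-length identity run", {
  set.seed(47)
  q <- list(name = "mir-100", sequence = MIR100)
  g <- c(s = paste0(rdna(300), rna_to_dna(MIR100), rdna(300)))
  hits <- scan_identity(g, q)
  expect_equal(max(hits$run_length), nchar(MIR100))
  best <- hits[1, ]
  expect_equal(best$start, 301)
  expect_equal(best$strand, "+")
  expect_true(best$covers_seed)
})

test_that("a 3' fragment gives a partial run that misses the seed", {
  set.seed(53)
  q <- list(name = "mir-x", sequence = MIR100)
  frag <- substr(rna_to_dna(MIR100), 8, 21)  # 14 nt
  g <- c(s = paste0(rdna(200), frag, rdna(200)))
  hits <- scan_identity(g, q)
  expect_equal(max(hits$run_length), 14)
  expect_false(hits$covers_seed[1])
  expect_equal(hits$q_start[1], 8)
})

test_that("minus-strand hits report query coordinates correctly", {
  set.seed(59)
  q <- list(name = "mir-x", sequence = MIR2022)
  g <- c(s = paste0(rdna(150), revcomp(rna_to_dna(MIR2022)), rdna(150)))
  hits <- scan_identity(g, q)
  best <- hits[1, ]
  expect_equal(best$strand, "-")
  expect_equal(best$run_length, nchar(MIR2022))
  expect_true(best$covers_seed)
  expect_equal(best$start, 151)
})

test_that("identity runs match a brute-force per-offset oracle", {
  longest_run_at <- function(pat, subj, g0) {
    # longest identity run of pat aligned with subj starting at g0
    best <- 0L; cur <- 0L
    for (t in seq_len(nchar(pat))) {
      gpos <- g0 + t - 1L
      same <- gpos >= 1 && gpos <= nchar(subj) &&
        substr(pat, t, t) == substr(subj, gpos, gpos)
      cur <- if (same) cur + 1L else 0L
      best <- max(best, cur)
    }
    best
  }
  set.seed(61)
  q <- list(name = "mir-x", sequence = MIR100)
  pat <- rna_to_dna(MIR100)
  frag <- substr(pat, 5, 20)
  g <- c(s = paste0(rdna(120), frag, rdna(120)))
  hits <- scan_identity(g, q, min_run = 11)
  oracle_best <- max(vapply(seq_len(nchar(g[["s"]])), function(g0) {
    longest_run_at(pat, g[["s"]], g0 - 0L)
  }, integer(1)))
  expect_equal(max(hits$run_length), oracle_best)
})

test_that("random genomes rarely contain long identity runs", {
  q <- list(name = "mir-x", sequence = MIR100)
  set.seed(67)
  runs <- vapply(1:5, function(i) {
    g <- c(s = rdna(1000))
    h <- scan_identity(g, q, min_run = 11)
    if (nrow(h)) max(h$run_length) else 0L
  }, integer(1))
  expect_true(all(runs < 14))
})

pred <- function(start, end, method, seq_id = "s", strand = "+") {
  data.frame(seq_id = seq_id, start = start, end = end, strand = strand,
             method = method, stringsAsFactors = FALSE)
}

test_that("consensus keeps shared loci and drops sample-specific ones", {
  s1 <- rbind(pred(100, 160, "M1"), pred(500, 560, "M1"))
  s2 <- rbind(pred(110, 150, "M2"))
  out <- consensus_filter(list(s1, s2), primary_method = "M1")
  expect_equal(nrow(out), 1)
  expect_equal(out$start, 100)
  expect_equal(out$n_methods, 2)
  expect_equal(out$methods, "M1,M2")
  # strandedness matters
  s2b <- pred(110, 150, "M2", strand = "-")
  expect_equal(nrow(consensus_filter(list(s1, s2b))), 0)
  # empty intersection
  expect_equal(nrow(consensus_filter(list(s1, pred(900, 950, "M2")))), 0)
})

test_that("method support ranks retained loci", {
  s1 <- rbind(pred(100, 160, "M1"), pred(500, 560, "M1"), pred(500, 560, "M2"))
  s2 <- rbind(pred(100, 160, "M1"), pred(500, 560, "M1"))
  out <- consensus_filter(list(s1, s2), primary_method = "M1")
  expect_equal(out$start, c(500, 100))
  expect_equal(out$n_methods, c(2, 1))
})

test_that("a single sample passes through with a warning", {
  expect_warning(out <- consensus_filter(list(pred(1, 50, "M1"))), "single")
  expect_equal(nrow(out), 1)
})

canonical_locus_fixture <- function(seed, scatter = FALSE) {
  set.seed(seed)
  stem <- rdna(26)
  hp <- paste0(stem, "ACAAA", revcomp(stem), "GT")
  g <- c(s = paste0(rdna(150), hp, rdna(150)))
  locus <- data.frame(seq_id = "s", start = 151L,
                      end = 150L + nchar(hp), strand = "+",
                      stringsAsFactors = FALSE)
  st <- fold_hairpin(dna_to_rna(hp))
  mk_aln <- function(starts, ends, counts) {
    data.frame(read = "x", seq_id = "s", start = starts, end = ends,
               strand = "+", mismatches = 0L, read_id = "r",
               read_count = counts, n_hits = 1L, stringsAsFactors = FALSE)
  }
  aln <- if (!scatter) {
    # tight mature stack at the 5' arm start, star stack at the duplex
    # partner position, a couple of jittered ends
    pairs <- st$pairs
    partner <- integer(nchar(hp))
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
    star5_rel <- partner[22 - 2]
    mk_aln(starts = 150L + c(rep(1L, 16), 2L, rep(star5_rel, 4)),
           ends = 150L + c(rep(22L, 16), 23L, rep(star5_rel + 21L, 4)),
           counts = c(rep(1L, 17), rep(1L, 4)))
  } else {
    starts <- 150L + seq(1L, nchar(hp) - 20L, by = 2L)
    mk_aln(starts, starts + 20L, rep(1L, length(starts)))
  }
  list(locus = locus, aln = aln, st = st)
}

test_that("a tight mature/star stack classifies as plausible", {
  fx <- canonical_locus_fixture(71)
  sig <- classify_locus(fx$locus, fx$aln, fx$st)
  expect_equal(sig$classification, "plausible")
  expect_gte(sig$mature_stack_fraction, 0.5)
  expect_lte(sig$end_heterogeneity, 2)
})

test_that("uniform read scatter classifies as atypical", {
  fx <- canonical_locus_fixture(73, scatter = TRUE)
  sig <- classify_locus(fx$locus, fx$aln, fx$st)
  expect_equal(sig$classification, "atypical")
  expect_true(length(sig$reasons) >= 1)
})

test_that("an unexpressed locus is atypical with reason no expression", {
  fx <- canonical_locus_fixture(79)
  sig <- classify_locus(fx$locus, fx$aln[0, ], fx$st)
  expect_equal(sig$classification, "atypical")
  expect_equal(sig$reasons, "no expression")
})

test_that("a star stack off the duplex register is flagged", {
  fx <- canonical_locus_fixture(83)
  aln <- fx$aln
  star_rows <- aln$start > 150L + 30L
  aln$start[star_rows] <- aln$start[star_rows] + 8L
  aln$end[star_rows] <- aln$end[star_rows] + 8L
  sig <- classify_locus(fx$locus, aln, fx$st)
  expect_true("star duplex offset" %in% sig$reasons)
})
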