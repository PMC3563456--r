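#' Weights for the mirtron structure score
#'
#' The structure score is a fixed logistic combination of hairpin features,
#' rewarding long stems and high paired fraction, preferring terminal loops
#' in a 4–20 nt window, and penalising bulges and overhangs beyond the 2 nt
#' expected of a spliced pre-miRNA. Monotone increasing in `stem_len` and
#' `paired_fraction` with everything else fixed.
#'
#' @param intercept,stem,paired_fraction,loop_window,bulge,overhang_excess
#'   logistic coefficients; `loop_window`, `bulge` and `overhang_excess` are
#'   penalties and must be <= 0.
#' @param loop_min,loop_max preferred terminal-loop window in nt.
#' @return named list of class `mirtron_score_weights`.
#' @export
mirtron_score_weights <- function(intercept = -6, stem = 0.25,
                                  paired_fraction = 6, loop_window = -0.4,
                                  bulge = -0.5, overhang_excess = -0.3,
                                  loop_min = 4L, loop_max = 20L) {
  stopifnot(stem > 0, paired_fraction > 0, loop_window <= 0, bulge <= 0,
            overhang_excess <= 0)
  structure(list(intercept = intercept, stem = stem,
                 paired_fraction = paired_fraction,
                 loop_window = loop_window, bulge = bulge,
                 overhang_excess = overhang_excess,
                 loop_min = as.integer(loop_min),
                 loop_max = as.integer(loop_max)),
            class = "mirtron_score_weights")
}

#' Score a candidate's hairpin quality on [0, 1]
#'
#' @param features a `hairpin_features` object from [extract_features()].
#' @param weights a [mirtron_score_weights()] object.
#' @return numeric score in (0, 1).
#' @export
score_mirtron_structure <- function(features, weights = mirtron_score_weights()) {
  loop_pen <- max(0L, weights$loop_min - features$loop_len) +
    max(0L, features$loop_len - weights$loop_max)
  over_pen <- max(0L, features$overhang5 - 2L) + max(0L, features$overhang3 - 2L)
  z <- weights$intercept +
    weights$stem * features$stem_len +
    weights$paired_fraction * features$paired_fraction +
    weights$loop_window * loop_pen +
    weights$bulge * features$n_bulges +
    weights$overhang_excess * over_pen
  plogis(z)
}

read_five_end <- function(alignments) {
  ifelse(alignments$strand == "+", alignments$start, alignments$end)
}

read_three_end <- function(alignments) {
  ifelse(alignments$strand == "+", alignments$end, alignments$start)
}

#' Count splice-site-anchored reads for one intron
#'
#' A read supports the 5' splice site when it maps in the correct
#' orientation (read strand equal to the intron strand) and its
#' transcript-orientation 5' end lies within `buffer` nt of the donor
#' position; analogously the read's 3' end for the acceptor. A read
#' satisfying both conditions counts once per site. `n5`/`n3` sum the
#' collapsed multiplicities (i.e. raw reads); `distinct5`/`distinct3` count
#' distinct collapsed sequences; `unique5`/`unique3` restrict the raw
#' tallies to uniquely-mapping reads.
#'
#' @param intron one-row intron data.frame (with `donor_pos`,
#'   `acceptor_pos`, `strand`, `seq_id`).
#' @param alignments alignment data.frame from [map_reads()].
#' @param buffer splice-site buffer in nt (default 3).
#' @return list of class `splice_signature` with fields `n5`, `n3`, `total`,
#'   `unique5`, `unique3`, `distinct5`, `distinct3`.
#' @export
count_splice_reads <- function(intron, alignments, buffer = 3L) {
  sig <- function(n5 = 0L, n3 = 0L, u5 = 0L, u3 = 0L, d5 = 0L, d3 = 0L) {
    structure(list(n5 = n5, n3 = n3, total = n5 + n3, unique5 = u5,
                   unique3 = u3, distinct5 = d5, distinct3 = d3),
              class = "splice_signature")
  }
  if (nrow(alignments) == 0) return(sig())
  a <- alignments[alignments$seq_id == intron$seq_id &
                    alignments$strand == intron$strand, , drop = FALSE]
  if (nrow(a) == 0) return(sig())
  count_col <- if (!is.null(a$read_count)) a$read_count else rep(1L, nrow(a))
  n_hits <- if (!is.null(a$n_hits)) a$n_hits else rep(1L, nrow(a))
  at5 <- abs(read_five_end(a) - intron$donor_pos) <= buffer
  at3 <- abs(read_three_end(a) - intron$acceptor_pos) <= buffer
  sig(n5 = sum(count_col[at5]), n3 = sum(count_col[at3]),
      u5 = sum(count_col[at5 & n_hits == 1L]),
      u3 = sum(count_col[at3 & n_hits == 1L]),
      d5 = sum(at5), d3 = sum(at3))
}

#' Fold, score and count reads for a set of intron candidates
#'
#' Candidates whose sequence contains N are excluded before folding
#' (undefined base pairing). Returns one row per surviving candidate with
#' hairpin features, the structure score and the splice signature.
#'
#' @param introns intron data.frame with sequences ([attach_sequence()]).
#' @param alignments alignment data.frame from [map_reads()].
#' @param buffer splice-site buffer in nt.
#' @param weights [mirtron_score_weights()] for the structure score.
#' @param fold_weights [pair_weights()] for the folder.
#' @param min_loop folder minimum loop.
#' @return data.frame with intron columns plus `dotbracket`, `fold_score`,
#'   `stem_len`, `loop_len`, `paired_fraction`, `n_bulges`,
#'   `structure_score`, `n5`, `n3`, `splice_total`, `unique5`, `unique3`,
#'   `distinct5`, `distinct3`.
#' @export
screen_candidates <- function(introns, alignments, buffer = 3L,
                              weights = mirtron_score_weights(),
                              fold_weights = pair_weights(), min_loop = 3L) {
  introns <- introns[!grepl("N", introns$sequence, fixed = TRUE), ,
                     drop = FALSE]
  if (nrow(introns) == 0) {
    out <- introns
    for (col in c("dotbracket", "fold_score", "stem_len", "loop_len",
                  "paired_fraction", "n_bulges", "structure_score", "n5",
                  "n3", "splice_total", "unique5", "unique3", "distinct5",
                  "distinct3")) out[[col]] <- numeric(0)
    return(out)
  }
  rows <- lapply(seq_len(nrow(introns)), function(i) {
    st <- fold_hairpin(introns$sequence[i], min_loop = min_loop,
                       weights = fold_weights)
    ft <- extract_features(st)
    sg <- count_splice_reads(introns[i, ], alignments, buffer = buffer)
    data.frame(dotbracket = st$dotbracket, fold_score = st$score,
               stem_len = ft$stem_len, loop_len = ft$loop_len,
               paired_fraction = ft$paired_fraction, n_bulges = ft$n_bulges,
               structure_score = score_mirtron_structure(ft, weights),
               n5 = sg$n5, n3 = sg$n3, splice_total = sg$total,
               unique5 = sg$unique5, unique3 = sg$unique3,
               distinct5 = sg$distinct5, distinct3 = sg$distinct3,
               stringsAsFactors = FALSE)
  })
  out <- cbind(introns, do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Attach the three candidate rankings
#'
#' `rank_structure` orders by descending structure score, `rank_reads` by
#' descending splice-anchored read total, and `rank_combined` by ascending
#' sum of the first two ranks — the intersection-style ranking in which only
#' candidates good on both axes rise to the top. All ties break on
#' (seq_id, start) so each ranking is a deterministic permutation of 1..N.
#'
#' @param candidates data.frame from [screen_candidates()].
#' @return the data.frame with `rank_structure`, `rank_reads`,
#'   `rank_combined` columns.
#' @export
rank_candidates <- function(candidates) {
  n <- nrow(candidates)
  if (n == 0) {
    candidates$rank_structure <- integer(0)
    candidates$rank_reads <- integer(0)
    candidates$rank_combined <- integer(0)
    return(candidates)
  }
  rank_by <- function(key) {
    ord <- order(-key, candidates$seq_id, candidates$start)
    rk <- integer(n)
    rk[ord] <- seq_len(n)
    rk
  }
  candidates$rank_structure <- rank_by(candidates$structure_score)
  candidates$rank_reads <- rank_by(candidates$splice_total)
  candidates$rank_combined <- rank_by(-(candidates$rank_structure +
                                          candidates$rank_reads))
  candidates
}

#' Run the mirtron screen over a length window
#'
#' Filters introns to the window, screens and ranks them. The core window is
#' `[50, 120]` nt; [extended_length_screen()] applies the identical pipeline
#' to the disjoint extension window `[121, 150]` nt and is reported
#' separately.
#'
#' @param introns intron data.frame with sequences.
#' @param alignments alignment data.frame.
#' @param bounds inclusive length window, `c(min, max)`.
#' @param ... passed to [screen_candidates()].
#' @return ranked candidate data.frame.
#' @export
mirtron_screen <- function(introns, alignments, bounds = c(50L, 120L), ...) {
  win <- filter_by_length(introns, bounds[1], bounds[2])
  rank_candidates(screen_candidates(win, alignments, ...))
}

#' @rdname mirtron_screen
#' @export
extended_length_screen <- function(introns, alignments,
                                   bounds = c(121L, 150L), ...) {
  mirtron_screen(introns, alignments, bounds = bounds, ...)
}

#' Write the screen report TSV
#'
#' One row per candidate with 1-based inclusive coordinates, strand, length,
#' structure score, dot-bracket, splice-site read counts and the three
#' ranks, ordered by the combined ranking.
#'
#' @param candidates ranked data.frame from [mirtron_screen()].
#' @param path output TSV path.
#' @param top_bed optional BED6 path for the top-`k` combined candidates.
#' @param k number of candidates for `top_bed`.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(candidates, path, top_bed = NULL, k = 5L) {
  cols <- c("seq_id", "start", "end", "strand", "length", "structure_score",
            "dotbracket", "n5", "n3", "splice_total", "unique5", "unique3",
            "distinct5", "distinct3", "rank_structure", "rank_reads",
            "rank_combined")
  out <- candidates[order(candidates$rank_combined), cols, drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(top_bed) && nrow(out) > 0) {
    top <- out[seq_len(min(k, nrow(out))), , drop = FALSE]
    top$score <- top$splice_total
    write_bed6(top, top_bed)
  }
  invisible(path)
}
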