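#' Read known mature miRNAs from a miRBase-style FASTA
#'
#' @param fasta_path mature-miRNA FASTA (RNA or DNA alphabet).
#' @return data.frame with `name`, `sequence` (RNA, uppercase), `seed`
#'   (positions 2–7).
#' @export
read_matures <- function(fasta_path) {
  set <- Biostrings::readBStringSet(fasta_path)
  seqs <- toupper(dna_to_rna(as.character(set)))
  data.frame(name = sub("\\s.*$", "", names(set)), sequence = seqs,
             seed = vapply(seqs, seed_of, character(1), USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Seed of a mature miRNA
#'
#' The seed is nucleotides 2–7 (1-based, inclusive) of the mature sequence —
#' the primary determinant of target recognition and the homology criterion
#' used throughout the conservation screen.
#'
#' @param mature_sequence mature miRNA sequence (length >= 7).
#' @return the 6-nt seed string.
#' @export
seed_of <- function(mature_sequence) {
  if (nchar(mature_sequence) < 7) {
    stop("mature sequence shorter than 7 nt has no seed")
  }
  substr(mature_sequence, 2L, 7L)
}

#' Seed-and-arm homology match between a candidate and a known mature
#'
#' A candidate matches a known miRNA when the seeds (positions 2–7) are
#' identical and the remaining compared positions carry at most
#' `max_rest_mismatches` Hamming mismatches. Candidate and known sequences
#' of unequal length are compared over the shorter length, with the
#' overhanging 3' bases uncounted (3'-end length heterogeneity is common in
#' mature annotations). U and T are treated as equivalent.
#'
#' @param candidate candidate small-RNA sequence.
#' @param known one row of [read_matures()] (or a list with `name`,
#'   `sequence`).
#' @param arm which arm the known sequence represents (`"mature"` or
#'   `"star"`), recorded in the result.
#' @param max_rest_mismatches mismatch budget outside the seed (default 3).
#' @return `NULL` when the criterion fails, otherwise a list of class
#'   `seed_match` with `query`, `candidate`, `seed_identical`,
#'   `mismatches_rest`, `matched_arm`.
#' @export
match_mature <- function(candidate, known, arm = c("mature", "star"),
                         max_rest_mismatches = 3L) {
  arm <- match.arg(arm)
  cand <- toupper(dna_to_rna(candidate))
  ref <- toupper(dna_to_rna(known$sequence))
  m <- min(nchar(cand), nchar(ref))
  if (m < 7L) return(NULL)
  cand_c <- substr(cand, 1L, m)
  ref_c <- substr(ref, 1L, m)
  seed_ok <- substr(cand_c, 2L, 7L) == substr(ref_c, 2L, 7L)
  if (!seed_ok) return(NULL)
  rest_idx <- setdiff(seq_len(m), 2:7)
  cc <- strsplit(cand_c, "")[[1]]
  rr <- strsplit(ref_c, "")[[1]]
  mm <- sum(cc[rest_idx] != rr[rest_idx])
  if (mm > max_rest_mismatches) return(NULL)
  structure(list(query = known$name, candidate = candidate,
                 seed_identical = TRUE, mismatches_rest = as.integer(mm),
                 matched_arm = arm),
            class = "seed_match")
}

#' Screen candidate small RNAs against a table of known matures
#'
#' Applies [match_mature()] for every candidate x known pair over both arm
#' labels supplied, returning all matches as a data.frame.
#'
#' @param candidates character vector of candidate sequences (e.g. abundant
#'   collapsed reads), optionally named.
#' @param knowns data.frame from [read_matures()]; rows may represent mature
#'   or star arms via the `arm` column (defaults to "mature" for all).
#' @param max_rest_mismatches mismatch budget outside the seed.
#' @return data.frame of matches: `candidate_id`, `candidate`, `query`,
#'   `matched_arm`, `mismatches_rest`.
#' @export
screen_known_mirnas <- function(candidates, knowns, max_rest_mismatches = 3L) {
  ids <- names(candidates)
  if (is.null(ids)) ids <- sprintf("cand%d", seq_along(candidates))
  arms <- if (!is.null(knowns$arm)) knowns$arm else rep("mature", nrow(knowns))
  rows <- list()
  for (i in seq_along(candidates)) {
    for (j in seq_len(nrow(knowns))) {
      hit <- match_mature(candidates[i], knowns[j, ], arm = arms[j],
                          max_rest_mismatches = max_rest_mismatches)
      if (!is.null(hit)) {
        rows[[length(rows) + 1L]] <- data.frame(
          candidate_id = ids[i], candidate = candidates[i],
          query = hit$query, matched_arm = hit$matched_arm,
          mismatches_rest = hit$mismatches_rest, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(candidate_id = character(), candidate = character(),
                      query = character(), matched_arm = character(),
                      mismatches_rest = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Scan a genome for identity runs to a known mature miRNA
#'
#' For every genomic site on either strand, finds the longest contiguous
#' exact match (identity run) between the query and the genome, reporting
#' runs of at least `min_run` nt. Each hit records whether the run spans the
#' query's seed (positions 2–7). Implemented as an exact-word scan: every
#' `min_run`-mer of the query is located in the genome and extended
#' maximally in both directions; maximal runs are reported once.
#'
#' @param genome named character vector from [read_genome()].
#' @param query list or one-row data.frame with `name` and `sequence`
#'   (RNA or DNA); length must be at least `min_run`.
#' @param min_run minimum reported identity run in nt (default 11).
#' @return data.frame of hits: `query`, `seq_id`, `start`, `end`, `strand`,
#'   `run_length`, `q_start`, `q_end` (query coordinates of the run),
#'   `covers_seed`.
#' @export
scan_identity <- function(genome, query, min_run = 11L) {
  qseq <- toupper(rna_to_dna(query$sequence))
  m <- nchar(qseq)
  if (m < min_run) stop("query shorter than min_run (", min_run, " nt)")
  empty <- data.frame(query = character(), seq_id = character(),
                      start = integer(), end = integer(),
                      strand = character(), run_length = integer(),
                      q_start = integer(), q_end = integer(),
                      covers_seed = logical(), stringsAsFactors = FALSE)
  rows <- list()
  for (sid in names(genome)) {
    subj <- genome[[sid]]
    nlen <- nchar(subj)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") qseq else revcomp(qseq)
      for (off in seq_len(m - min_run + 1L)) {
        word <- substr(pat, off, off + min_run - 1L)
        hits <- gregexpr(word, subj, fixed = TRUE)[[1]]
        if (hits[1] == -1L) next
        for (g in hits) {
          # extend maximally left and right
          qs <- off; ge_start <- g
          while (qs > 1L && ge_start > 1L &&
                 substr(pat, qs - 1L, qs - 1L) ==
                 substr(subj, ge_start - 1L, ge_start - 1L)) {
            qs <- qs - 1L; ge_start <- ge_start - 1L
          }
          qe <- off + min_run - 1L; ge_end <- g + min_run - 1L
          while (qe < m && ge_end < nlen &&
                 substr(pat, qe + 1L, qe + 1L) ==
                 substr(subj, ge_end + 1L, ge_end + 1L)) {
            qe <- qe + 1L; ge_end <- ge_end + 1L
          }
          # query coordinates of the run, in the query's own orientation
          if (strand == "+") {
            q1 <- qs; q2 <- qe
          } else {
            q1 <- m - qe + 1L; q2 <- m - qs + 1L
          }
          rows[[length(rows) + 1L]] <- data.frame(
            query = query$name, seq_id = sid, start = ge_start,
            end = ge_end, strand = strand, run_length = qe - qs + 1L,
            q_start = q1, q_end = q2,
            covers_seed = (q1 <= 2L && q2 >= 7L),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[c("seq_id", "start", "end", "strand")]), ,
             drop = FALSE]
  out <- out[order(-out$run_length, out$seq_id, out$start, out$strand), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-sample consensus filter for predicted miRNA loci
#'
#' Retains loci predicted (with at least one read) in every sample —
#' presence meaning a same-strand interval overlap between samples — and
#' ranks the retained loci by the number of distinct supporting methods
#' (union over samples, descending), with the designated primary method
#' breaking ties, then coordinates. A single sample passes through with a
#' warning, unranked by consensus.
#'
#' @param predictions_by_sample named list of per-sample data.frames with
#'   columns `seq_id`, `start`, `end`, `strand`, `method`.
#' @param primary_method method name used to break support-count ties.
#' @return data.frame of retained consensus loci (`seq_id`, `start`, `end`,
#'   `strand`, `n_methods`, `methods`, `primary_support`), ordered by rank.
#' @export
consensus_filter <- function(predictions_by_sample, primary_method = NULL) {
  stopifnot(is.list(predictions_by_sample), length(predictions_by_sample) >= 1)
  preds <- predictions_by_sample
  if (length(preds) == 1) {
    warning("single sample provided; consensus filter passes all loci through")
  }
  as_gr <- function(df) {
    GenomicRanges::GRanges(df$seq_id,
                           IRanges::IRanges(df$start, df$end),
                           strand = df$strand)
  }
  all_df <- do.call(rbind, lapply(seq_along(preds), function(s) {
    df <- preds[[s]]
    if (nrow(df) == 0) return(NULL)
    df$sample <- s
    df
  }))
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_methods = integer(), methods = character(),
                      primary_support = logical(), stringsAsFactors = FALSE)
  if (is.null(all_df) || nrow(all_df) == 0) return(empty)
  gr <- as_gr(all_df)
  loci <- GenomicRanges::reduce(gr)  # strand-aware merged loci
  ov <- GenomicRanges::findOverlaps(gr, loci)
  locus_of <- rep(NA_integer_, nrow(all_df))
  locus_of[S4Vectors::queryHits(ov)] <- S4Vectors::subjectHits(ov)
  keep <- vapply(seq_along(loci), function(l) {
    samples_here <- unique(all_df$sample[locus_of == l])
    length(samples_here) == length(preds)
  }, logical(1))
  if (!any(keep)) return(empty)
  out <- do.call(rbind, lapply(which(keep), function(l) {
    members <- all_df[locus_of == l, , drop = FALSE]
    methods <- sort(unique(members$method))
    data.frame(
      seq_id = as.character(GenomicRanges::seqnames(loci))[l],
      start = GenomicRanges::start(loci)[l],
      end = GenomicRanges::end(loci)[l],
      strand = as.character(GenomicRanges::strand(loci))[l],
      n_methods = length(methods),
      methods = paste(methods, collapse = ","),
      primary_support = !is.null(primary_method) &&
        primary_method %in% methods,
      stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_methods, -out$primary_support, out$seq_id,
                   out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Thresholds for the read-mapping-signature classifier
#'
#' Community miRNA-annotation criteria expressed as configurable thresholds:
#' a plausible locus concentrates at least `min_mature_fraction` of its
#' reads on one arm, those reads share a precise 5' end (mean absolute
#' displacement from the modal 5' end at most `max_end_heterogeneity` nt),
#' at most `max_loop_fraction` of reads fall in the terminal loop, and any
#' star reads sit at the duplex position implied by Dicer processing with a
#' 2-nt 3' overhang (within `star_offset_tol` nt).
#'
#' @param min_mature_fraction,max_end_heterogeneity,max_loop_fraction,star_offset_tol
#'   thresholds as described.
#' @return named list of class `signature_thresholds`.
#' @export
signature_thresholds <- function(min_mature_fraction = 0.5,
                                 max_end_heterogeneity = 2,
                                 max_loop_fraction = 0.1,
                                 star_offset_tol = 3L) {
  structure(list(min_mature_fraction = min_mature_fraction,
                 max_end_heterogeneity = max_end_heterogeneity,
                 max_loop_fraction = max_loop_fraction,
                 star_offset_tol = as.integer(star_offset_tol)),
            class = "signature_thresholds")
}

#' Classify a candidate locus by its read-mapping signature
#'
#' Projects same-strand alignments into locus coordinates (transcript
#' orientation), partitions the folded hairpin into 5' arm, terminal loop
#' and 3' arm from its longest duplex region, and tests the signature
#' criteria of [signature_thresholds()]. The mature arm is the arm holding
#' the modal read 5' end. A locus failing any criterion is `atypical`, with
#' the failing criteria listed in `reasons`; a locus without reads is
#' atypical with reason `"no expression"`.
#'
#' @param locus one-row data.frame (`seq_id`, `start`, `end`, `strand`).
#' @param alignments alignment data.frame from [map_reads()].
#' @param structure `hairpin_structure` of the locus RNA (transcript
#'   orientation), from [fold_hairpin()].
#' @param thresholds a [signature_thresholds()] object.
#' @return list of class `locus_signature`: `mature_stack_fraction`,
#'   `star_stack_fraction`, `loop_fraction`, `end_heterogeneity`,
#'   `classification` ("plausible"/"atypical"), `reasons`.
#' @export
classify_locus <- function(locus, alignments, structure,
                           thresholds = signature_thresholds()) {
  L <- locus$end - locus$start + 1L
  res <- function(classification, reasons, mf = 0, sf = 0, lf = 0,
                  het = NA_real_) {
    structure(list(mature_stack_fraction = mf, star_stack_fraction = sf,
                   loop_fraction = lf, end_heterogeneity = het,
                   classification = classification, reasons = reasons),
              class = "locus_signature")
  }
  a <- alignments[alignments$seq_id == locus$seq_id &
                    alignments$strand == locus$strand &
                    alignments$start <= locus$end &
                    alignments$end >= locus$start, , drop = FALSE]
  if (nrow(a) == 0) return(res("atypical", "no expression"))
  w <- if (!is.null(a$read_count)) a$read_count else rep(1L, nrow(a))
  # locus-relative 5' ends in transcript orientation
  g5 <- read_five_end(a)
  rel5 <- if (locus$strand == "+") g5 - locus$start + 1L else locus$end - g5 + 1L
  inside <- rel5 >= 1L & rel5 <= L
  a <- a[inside, , drop = FALSE]; w <- w[inside]; rel5 <- rel5[inside]
  if (nrow(a) == 0) return(res("atypical", "no expression"))
  total <- sum(w)

  # arm/loop partition from the longest duplex region of the fold
  pairs <- structure$pairs
  if (nrow(pairs) == 0) {
    return(res("atypical", "no hairpin", het = NA_real_))
  }
  ft <- extract_features(structure)
  # recover the main region's outer and inner pairs as in extract_features
  region_id <- integer(nrow(pairs)); region_id[1] <- 1L
  if (nrow(pairs) > 1) {
    for (p in 2:nrow(pairs)) {
      nested <- pairs[p, 1] > pairs[p - 1, 1] && pairs[p, 2] < pairs[p - 1, 2]
      region_id[p] <- region_id[p - 1] + ifelse(nested, 0L, 1L)
    }
  }
  main <- which.max(tabulate(region_id))
  mp <- pairs[region_id == main, , drop = FALSE]
  outer <- mp[1, ]; inner <- mp[nrow(mp), ]
  arm5 <- c(1L, inner[1])            # 5' arm (incl. leading overhang)
  loop_iv <- c(inner[1] + 1L, inner[2] - 1L)
  arm3 <- c(inner[2], L)             # 3' arm (incl. trailing overhang)

  in_loop <- rel5 >= loop_iv[1] & rel5 <= loop_iv[2]
  in_arm5 <- rel5 < loop_iv[1]
  in_arm3 <- rel5 > loop_iv[2]
  loop_fraction <- sum(w[in_loop]) / total

  mode_pos <- as.integer(names(which.max(tapply(w, rel5, sum))))
  mature_in_5 <- mode_pos < loop_iv[1]
  in_mature <- if (mature_in_5) in_arm5 else in_arm3
  in_star <- if (mature_in_5) in_arm3 else in_arm5
  mature_fraction <- sum(w[in_mature]) / total
  star_fraction <- sum(w[in_star]) / total
  het <- sum(w[in_mature] * abs(rel5[in_mature] - mode_pos)) /
    max(1, sum(w[in_mature]))

  reasons <- character(0)
  if (mode_pos >= loop_iv[1] && mode_pos <= loop_iv[2]) {
    reasons <- c(reasons, "modal read in loop")
  }
  if (mature_fraction < thresholds$min_mature_fraction) {
    reasons <- c(reasons, "mature_stack_fraction")
  }
  if (het > thresholds$max_end_heterogeneity) {
    reasons <- c(reasons, "end_heterogeneity")
  }
  if (loop_fraction > thresholds$max_loop_fraction) {
    reasons <- c(reasons, "loop_fraction")
  }
  # star duplex geometry: expected star 5' end is the pairing partner of
  # (mature 3' end - 2), leaving the 2-nt 3' overhang of Dicer products
  if (any(in_star) && any(in_mature)) {
    partner <- integer(L)
    partner[pairs[, 1]] <- pairs[, 2]
    partner[pairs[, 2]] <- pairs[, 1]
    lens <- a$end - a$start + 1L
    ml <- as.integer(names(which.max(tapply(w[in_mature], lens[in_mature],
                                            sum))))
    mature_end3 <- if (mature_in_5) mode_pos + ml - 1L else mode_pos - ml + 1L
    anchor <- if (mature_in_5) mature_end3 - 2L else mature_end3 + 2L
    anchor <- max(1L, min(L, anchor))
    # nearest paired base at or inside the anchor
    probe <- anchor
    while (probe >= 1L && probe <= L && partner[probe] == 0L) {
      probe <- probe + ifelse(mature_in_5, -1L, 1L)
    }
    if (probe < 1L || probe > L || partner[probe] == 0L) {
      reasons <- c(reasons, "star duplex unresolved")
    } else {
      expected_star5 <- partner[probe]
      star_mode <- as.integer(names(which.max(tapply(w[in_star],
                                                     rel5[in_star], sum))))
      if (abs(star_mode - expected_star5) > thresholds$star_offset_tol) {
        reasons <- c(reasons, "star duplex offset")
      }
    }
  }
  res(if (length(reasons)) "atypical" else "plausible", reasons,
      mf = mature_fraction, sf = star_fraction, lf = loop_fraction,
      het = het)
}
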