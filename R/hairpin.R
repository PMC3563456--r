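#' Base-pairing weights for hairpin folding
#'
#' The maximum-weight folder scores each admissible pair by stability class:
#' GC = 3, AU = 2, GU = 1 by default (mirroring relative duplex stability;
#' the weights are dimensionless). Symmetric by construction, so the fold
#' score is invariant under reverse complement.
#'
#' @param GC,AU,GU weights for the three pair classes.
#' @return named numeric vector.
#' @export
pair_weights <- function(GC = 3, AU = 2, GU = 1) c(GC = GC, AU = AU, GU = GU)

#' Fold a sequence into its maximum-weight nested pairing
#'
#' A Nussinov-style dynamic program over nested (pseudoknot-free) pairings:
#' each admissible pair (GC/AU/GU in either orientation) contributes its
#' weight, pairs must enclose at least `min_loop` unpaired bases, and the
#' structure maximising total weight is returned with a deterministic
#' traceback (the leftmost base is paired whenever a maximal structure allows
#' it, to its nearest admissible partner), so outputs are bit-stable.
#'
#' @param sequence RNA string over A/C/G/U (T is accepted and read as U);
#'   sequences containing N must be excluded upstream.
#' @param min_loop minimum unpaired bases enclosed by any pair (default 3).
#' @param weights a [pair_weights()] vector.
#' @return list of class `hairpin_structure`: `sequence`, `dotbracket`,
#'   `pairs` (two-column matrix of 1-based i < j), `score`.
#' @export
fold_hairpin <- function(sequence, min_loop = 3L, weights = pair_weights()) {
  seq_rna <- toupper(dna_to_rna(sequence))
  if (grepl("[^ACGU]", seq_rna)) {
    stop("invalid alphabet in sequence (need A/C/G/U): ", sequence)
  }
  if (nchar(seq_rna) < min_loop + 2L) {
    stop("sequence shorter than min_loop + 2 (", min_loop + 2L, " nt)")
  }
  res <- fold_dp(seq_rna, as.integer(min_loop), weights[["GC"]],
                 weights[["AU"]], weights[["GU"]])
  pairs <- cbind(i = res$i, j = res$j)
  if (nrow(pairs)) pairs <- pairs[order(pairs[, "i"]), , drop = FALSE]
  structure(list(sequence = seq_rna,
                 dotbracket = pairs_to_dotbracket(pairs, nchar(seq_rna)),
                 pairs = pairs, score = res$score),
            class = "hairpin_structure")
}

#' Convert between a pair list and dot-bracket notation
#'
#' @param pairs two-column matrix of 1-based (i, j) pairs with i < j.
#' @param n sequence length.
#' @return `pairs_to_dotbracket`: a dot-bracket string;
#'   `dotbracket_to_pairs`: the pair matrix (nesting is implied by matched
#'   brackets).
#' @export
pairs_to_dotbracket <- function(pairs, n) {
  db <- rep(".", n)
  if (nrow(pairs)) {
    db[pairs[, 1]] <- "("
    db[pairs[, 2]] <- ")"
  }
  paste(db, collapse = "")
}

#' @rdname pairs_to_dotbracket
#' @param dotbracket dot-bracket string over `(`, `.`, `)`.
#' @export
dotbracket_to_pairs <- function(dotbracket) {
  chars <- strsplit(dotbracket, "")[[1]]
  open <- integer(0)
  out <- list()
  for (p in seq_along(chars)) {
    if (chars[p] == "(") {
      open <- c(open, p)
    } else if (chars[p] == ")") {
      if (!length(open)) stop("unbalanced brackets")
      out[[length(out) + 1L]] <- c(open[length(open)], p)
      open <- open[-length(open)]
    }
  }
  if (length(open)) stop("unbalanced brackets")
  pairs <- if (length(out)) do.call(rbind, out) else
    matrix(integer(0), ncol = 2)
  colnames(pairs) <- c("i", "j")
  pairs[order(pairs[, "i"]), , drop = FALSE]
}

#' Exhaustive folding oracle
#'
#' Explicitly enumerates every nested pairing of the sequence (leftmost base
#' unpaired, or paired with each admissible partner, recursing into the
#' enclosed and remaining intervals), scores each enumerated structure by
#' summing its pair weights, and returns the maximum. Independent of the
#' dynamic program and deliberately guarded to short sequences, where full
#' enumeration is cheap.
#'
#' @inheritParams fold_hairpin
#' @return the maximum structure weight (numeric scalar).
#' @export
brute_force_fold <- function(sequence, min_loop = 3L,
                             weights = pair_weights()) {
  seq_rna <- toupper(dna_to_rna(sequence))
  n <- nchar(seq_rna)
  if (n > 14) stop("brute_force_fold is limited to sequences of <= 14 nt")
  bases <- strsplit(seq_rna, "")[[1]]
  wt <- function(a, b) {
    key <- paste0(a, b)
    if (key %in% c("GC", "CG")) return(weights[["GC"]])
    if (key %in% c("AU", "UA")) return(weights[["AU"]])
    if (key %in% c("GU", "UG")) return(weights[["GU"]])
    0
  }
  # every nested pairing of [i, j] as a list of pair lists
  enum <- function(i, j) {
    if (i >= j) return(list(list()))
    out <- enum(i + 1L, j)  # i unpaired
    if (j >= i + min_loop + 1L) {
      for (k in (i + min_loop + 1L):j) {
        if (wt(bases[i], bases[k]) <= 0) next
        for (a in enum(i + 1L, k - 1L)) {
          for (b in enum(k + 1L, j)) {
            out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
          }
        }
      }
    }
    out
  }
  score_of <- function(struct) {
    if (!length(struct)) return(0)
    sum(vapply(struct, function(p) wt(bases[p[1]], bases[p[2]]), numeric(1)))
  }
  max(vapply(enum(1L, n), score_of, numeric(1)))
}

#' Extract hairpin features from a folded structure
#'
#' Features feed the mirtron structure score. The stem is the longest
#' "duplex region": a maximal run of pairs, taken in order of their opening
#' base, in which each pair is nested directly inside the previous one
#' (branching starts a new region); interruptions within that run (either
#' side stepping by more than one base) are counted as bulges. The terminal
#' loop is the unpaired stretch enclosed by the innermost pair of the
#' longest region. Overhangs count unpaired bases outside the outermost
#' pair; a pairless structure reports its full length split at the midpoint
#' as the two overhangs.
#'
#' @param structure a `hairpin_structure` from [fold_hairpin()].
#' @return list of class `hairpin_features`: `stem_len`, `loop_len`,
#'   `paired_fraction`, `overhang5`, `overhang3`, `n_bulges`, `gu_fraction`.
#' @export
extract_features <- function(structure) {
  n <- nchar(structure$sequence)
  pairs <- structure$pairs
  if (nrow(pairs) == 0) {
    return(structure(list(stem_len = 0L, loop_len = 0L, paired_fraction = 0,
                          overhang5 = n %/% 2L, overhang3 = n - n %/% 2L,
                          n_bulges = 0L, gu_fraction = 0),
                     class = "hairpin_features"))
  }
  # Split pairs (ordered by opening base) into duplex regions: a region
  # continues while the next pair is nested inside the current one.
  region_id <- integer(nrow(pairs))
  region_id[1] <- 1L
  if (nrow(pairs) > 1) {
    for (p in 2:nrow(pairs)) {
      nested <- pairs[p, 1] > pairs[p - 1, 1] && pairs[p, 2] < pairs[p - 1, 2]
      region_id[p] <- region_id[p - 1] + ifelse(nested, 0L, 1L)
    }
  }
  sizes <- tabulate(region_id)
  main <- which.max(sizes)
  main_pairs <- pairs[region_id == main, , drop = FALSE]
  # bulges: interruptions between consecutive pairs of any region
  n_bulges <- 0L
  if (nrow(pairs) > 1) {
    for (p in 2:nrow(pairs)) {
      if (region_id[p] != region_id[p - 1]) next
      gap5 <- pairs[p, 1] - pairs[p - 1, 1] - 1L
      gap3 <- pairs[p - 1, 2] - pairs[p, 2] - 1L
      if (gap5 > 0L || gap3 > 0L) n_bulges <- n_bulges + 1L
    }
  }
  # the innermost pair of a region never encloses further pairs (they would
  # directly follow it in opening-base order and extend the region)
  inner <- main_pairs[nrow(main_pairs), ]
  loop_len <- as.integer(inner[2] - inner[1] - 1L)
  base <- paste0(substr(structure$sequence, pairs[, 1], pairs[, 1]),
                 substr(structure$sequence, pairs[, 2], pairs[, 2]))
  structure(list(
    stem_len = nrow(main_pairs),
    loop_len = loop_len,
    paired_fraction = 2 * nrow(pairs) / n,
    overhang5 = as.integer(min(pairs[, 1]) - 1L),
    overhang3 = as.integer(n - max(pairs[, 2])),
    n_bulges = n_bulges,
    gu_fraction = mean(base %in% c("GU", "UG"))
  ), class = "hairpin_features")
}

#' Write structures in Vienna-style text layout
#'
#' One record per structure: a header line, the sequence line, and the
#' dot-bracket line with the score in parentheses.
#'
#' @param structures list of `hairpin_structure` objects, optionally named.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vienna <- function(structures, path) {
  ids <- names(structures)
  if (is.null(ids)) ids <- sprintf("structure_%d", seq_along(structures))
  lines <- unlist(lapply(seq_along(structures), function(i) {
    s <- structures[[i]]
    c(paste0(">", ids[i]), s$sequence,
      sprintf("%s (%g)", s$dotbracket, s$score))
  }))
  writeLines(lines, path)
  invisible(path)
}
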