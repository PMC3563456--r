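#' Pipeline configuration
#'
#' Collects input paths and every stage parameter with its default: the
#' core and extended intron length windows (50–120 and 121–150 nt), the
#' 3-nt splice-site buffer, the 2-mismatch mapping budget, the seed/arm
#' homology criterion (seed 2–7 identical, at most 3 mismatches elsewhere),
#' trim and filter parameters and the signature thresholds. All parameters
#' are echoed into the summary header for reproducibility.
#'
#' @param genome_fasta,gff,fastqs,matures_fasta,blocklist_fasta input paths
#'   (`fastqs` is a character vector, one file per sample; `matures_fasta`
#'   and `blocklist_fasta` may be `NULL`).
#' @param out_dir directory for all outputs.
#' @param core_bounds,extended_bounds inclusive intron length windows.
#' @param buffer splice-site buffer in nt.
#' @param max_mismatches mapping mismatch budget.
#' @param index_k mapper seed length; the default 6 keeps the pigeonhole
#'   guarantee (`floor(read_len / k) >= max_mismatches + 1`) for the
#'   shortest accepted read (18 nt) at the 2-mismatch budget.
#' @param trim a [trim_params()] object.
#' @param score_weights a [mirtron_score_weights()] object.
#' @param fold_weights a [pair_weights()] vector; `min_loop` the folder
#'   minimum loop.
#' @param thresholds a [signature_thresholds()] object.
#' @param max_rest_mismatches non-seed mismatch budget for homology matches.
#' @param top_k candidates reported per ranking in the summary.
#' @param min_locus_reads collapsed-read support needed before a locus is
#'   classified.
#' @return list of class `run_config`.
#' @export
run_config <- function(genome_fasta, gff, fastqs, matures_fasta = NULL,
                       blocklist_fasta = NULL, out_dir = tempfile("mirscreen"),
                       core_bounds = c(50L, 120L),
                       extended_bounds = c(121L, 150L), buffer = 3L,
                       max_mismatches = 2L, index_k = 6L,
                       trim = trim_params(),
                       score_weights = mirtron_score_weights(),
                       fold_weights = pair_weights(), min_loop = 3L,
                       thresholds = signature_thresholds(),
                       max_rest_mismatches = 3L, top_k = 5L,
                       min_locus_reads = 2L) {
  structure(as.list(environment()), class = "run_config")
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste0(...)))
}

#' Run the full absence-screening pipeline
#'
#' Executes trim, filter, collapse, map, the core and extended mirtron
#' screens, the known-miRNA homology screen (when a mature FASTA is given)
#' and locus classification, writing all TSV/BED artifacts, a summary text
#' and a MANIFEST into `config$out_dir`. Any stage error aborts with the
#' stage named; files written up to that point are retained and the
#' MANIFEST notes incompleteness.
#'
#' @param config a [run_config()].
#' @return list of class `screen_results` with elements `per_sample`
#'   (stage read counts), `alignments`, `introns`, `core`, `extended`
#'   (ranked candidate tables), `homology`, `loci` (classified locus
#'   table), `config`.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- character(0)
  done <- FALSE
  on.exit({
    mf <- file.path(config$out_dir, "MANIFEST")
    hdr <- if (done) "# complete" else "# INCOMPLETE: pipeline aborted"
    files <- file.path(config$out_dir, manifest)
    sums <- tools::md5sum(files[file.exists(files)])
    writeLines(c(hdr, sprintf("%s  %s", sums, basename(names(sums)))), mf)
  })
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage [", stage, "] failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  t0 <- Sys.time()

  genome <- wrap("genome_io", read_genome(config$genome_fasta))
  exons <- wrap("genome_io", read_exons(config$gff))
  introns <- wrap("genome_io",
                  attach_sequence(derive_introns(exons), genome))
  stage_msg("genome_io", length(genome), " sequences, ", nrow(introns),
            " introns")

  per_sample <- list()
  collapsed_all <- list()
  for (s in seq_along(config$fastqs)) {
    raw <- wrap("smallrna_prep", read_fastq_reads(config$fastqs[s]))
    trimmed <- wrap("smallrna_prep", trim_adapter(raw, config$trim))
    filtered <- wrap("smallrna_prep",
                     quality_length_filter(trimmed, config$trim))
    filtered <- wrap("smallrna_prep",
                     subtract_blocklist(filtered, config$blocklist_fasta))
    collapsed <- wrap("smallrna_prep", collapse_reads(filtered))
    per_sample[[s]] <- data.frame(sample = s, raw = nrow(raw),
                                  filtered = nrow(filtered),
                                  collapsed = nrow(collapsed))
    collapsed$sample <- rep(s, nrow(collapsed))
    collapsed_all[[s]] <- collapsed
    write_collapsed(collapsed,
                    tsv_path = file.path(config$out_dir,
                                         sprintf("collapsed_s%d.tsv", s)))
    manifest <- c(manifest, sprintf("collapsed_s%d.tsv", s))
    stage_msg("smallrna_prep", "sample ", s, ": ", nrow(raw), " raw -> ",
              nrow(filtered), " kept -> ", nrow(collapsed), " distinct")
  }
  # pool distinct sequences across samples for mapping; per-sample counts
  # stay available in collapsed_all for the consensus logic
  pooled <- collapse_reads(do.call(rbind, lapply(collapsed_all, function(x) {
    x[c("read_id", "sequence", "count")]
  })))

  index <- wrap("read_mapper", build_index(genome, config$index_k))
  alignments <- wrap("read_mapper",
                     map_reads(pooled, index, genome, config$max_mismatches))
  mapped_frac <- if (nrow(pooled)) {
    sum(pooled$count[pooled$sequence %in% unique(alignments$read)]) /
      sum(pooled$count)
  } else 0
  write_alignments(alignments,
                   file.path(config$out_dir, "alignments.tsv"),
                   file.path(config$out_dir, "alignments.bed"))
  manifest <- c(manifest, "alignments.tsv", "alignments.bed")
  stage_msg("read_mapper", nrow(alignments), " alignments, mapped fraction ",
            sprintf("%.3f", mapped_frac))

  core <- wrap("mirtron_screen",
               mirtron_screen(introns, alignments,
                              bounds = config$core_bounds,
                              buffer = config$buffer,
                              weights = config$score_weights,
                              fold_weights = config$fold_weights,
                              min_loop = config$min_loop))
  extended <- wrap("mirtron_screen",
                   extended_length_screen(introns, alignments,
                                          bounds = config$extended_bounds,
                                          buffer = config$buffer,
                                          weights = config$score_weights,
                                          fold_weights = config$fold_weights,
                                          min_loop = config$min_loop))
  write_screen_report(core, file.path(config$out_dir, "mirtron_core.tsv"),
                      top_bed = file.path(config$out_dir, "mirtron_top.bed"),
                      k = config$top_k)
  write_screen_report(extended,
                      file.path(config$out_dir, "mirtron_extended.tsv"))
  manifest <- c(manifest, "mirtron_core.tsv", "mirtron_top.bed",
                "mirtron_extended.tsv")
  stage_msg("mirtron_screen", nrow(core), " core + ", nrow(extended),
            " extended candidates")

  homology <- NULL
  if (!is.null(config$matures_fasta)) {
    matures <- wrap("mirna_search", read_matures(config$matures_fasta))
    abundant <- pooled$sequence[pooled$count >= 2]
    homology <- wrap("mirna_search", {
      sm <- screen_known_mirnas(dna_to_rna(abundant), matures,
                                config$max_rest_mismatches)
      runs <- do.call(rbind, lapply(seq_len(nrow(matures)), function(i) {
        scan_identity(genome, matures[i, ])
      }))
      list(seed_matches = sm, identity_hits = runs)
    })
    write.table(homology$seed_matches,
                file.path(config$out_dir, "seed_matches.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(homology$identity_hits,
                file.path(config$out_dir, "identity_hits.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    manifest <- c(manifest, "seed_matches.tsv", "identity_hits.tsv")
    stage_msg("mirna_search", nrow(homology$seed_matches), " seed matches, ",
              nrow(homology$identity_hits), " identity hits")
  }

  loci <- wrap("classify", classify_read_clusters(genome, alignments,
                                                  config))
  write.table(loci, file.path(config$out_dir, "locus_signatures.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- c(manifest, "locus_signatures.tsv")
  stage_msg("classify", nrow(loci), " loci classified (",
            sum(loci$classification == "plausible"), " plausible)")

  results <- structure(list(
    per_sample = do.call(rbind, per_sample), mapped_fraction = mapped_frac,
    alignments = alignments, introns = introns, core = core,
    extended = extended, homology = homology, loci = loci,
    config = config), class = "screen_results")
  write_summary(results, file.path(config$out_dir, "summary.txt"))
  manifest <- c(manifest, "summary.txt")
  stage_msg("report", "done in ",
            sprintf("%.1f s", as.numeric(difftime(Sys.time(), t0, "secs"))))
  done <- TRUE
  results
}

#' Cluster alignments into candidate expressed loci
#'
#' Merges same-strand alignments lying within `max_gap` nt of each other
#' into loci and keeps those supported by at least `min_reads` raw reads —
#' the "present in at least one read" notion used by the cross-sample
#' consensus filter.
#'
#' @param alignments alignment data.frame from [map_reads()].
#' @param min_reads minimum summed read count per locus.
#' @param max_gap maximum within-locus alignment gap in nt.
#' @param method optional method label attached to each locus.
#' @return data.frame `seq_id`, `start`, `end`, `strand`, `n_reads`
#'   (and `method` when given).
#' @export
cluster_alignments <- function(alignments, min_reads = 1L, max_gap = 20L,
                               method = NULL) {
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_reads = numeric(), stringsAsFactors = FALSE)
  if (!is.null(method)) empty$method <- character()
  if (nrow(alignments) == 0) return(empty)
  gr <- GenomicRanges::GRanges(alignments$seq_id,
                               IRanges::IRanges(alignments$start,
                                                alignments$end),
                               strand = alignments$strand)
  clusters <- GenomicRanges::reduce(gr, min.gapwidth = max_gap)
  ov <- GenomicRanges::findOverlaps(gr, clusters)
  w <- if (!is.null(alignments$read_count)) alignments$read_count else
    rep(1L, nrow(alignments))
  counts <- tapply(w[S4Vectors::queryHits(ov)],
                   S4Vectors::subjectHits(ov), sum)
  idx <- as.integer(names(counts))
  out <- data.frame(
    seq_id = as.character(GenomicRanges::seqnames(clusters))[idx],
    start = GenomicRanges::start(clusters)[idx],
    end = GenomicRanges::end(clusters)[idx],
    strand = as.character(GenomicRanges::strand(clusters))[idx],
    n_reads = as.numeric(counts), stringsAsFactors = FALSE)
  out <- out[out$n_reads >= min_reads, , drop = FALSE]
  if (!is.null(method)) out$method <- method
  out <- out[order_by_locus(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cluster alignments into candidate loci and classify their signatures
#'
#' Groups same-strand alignments into read clusters (within `max_gap` nt),
#' keeps clusters with at least `config$min_locus_reads` collapsed reads,
#' folds a window around each cluster and applies [classify_locus()].
#'
#' @param genome named character vector.
#' @param alignments alignment data.frame from [map_reads()].
#' @param config a [run_config()].
#' @param max_gap maximum gap within a cluster; `pad` folding window padding.
#' @return data.frame of loci with signature fields and classification.
#' @export
classify_read_clusters <- function(genome, alignments, config,
                                   max_gap = 20L, pad = 40L) {
  empty <- data.frame(seq_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      total_reads = numeric(), mature_stack_fraction = numeric(),
                      star_stack_fraction = numeric(),
                      loop_fraction = numeric(),
                      end_heterogeneity = numeric(),
                      classification = character(), reasons = character(),
                      stringsAsFactors = FALSE)
  if (nrow(alignments) == 0) return(empty)
  clusters <- cluster_alignments(alignments,
                                 min_reads = config$min_locus_reads,
                                 max_gap = max_gap)
  # drop huge clusters (rRNA-like pileups) that are not hairpin-locus-sized
  clusters <- clusters[clusters$end - clusters$start + 1L <= 200L, ,
                       drop = FALSE]
  rows <- lapply(seq_len(nrow(clusters)), function(cl) {
    sid <- clusters$seq_id[cl]
    strand <- clusters$strand[cl]
    start <- max(1L, clusters$start[cl] - pad)
    end <- min(nchar(genome[[sid]]), clusters$end[cl] + pad)
    locus <- data.frame(seq_id = sid, start = start, end = end,
                        strand = strand, stringsAsFactors = FALSE)
    lt <- substr(genome[[sid]], start, end)
    if (strand == "-") lt <- revcomp(lt)
    if (grepl("N", lt, fixed = TRUE)) return(NULL)
    st <- fold_hairpin(dna_to_rna(lt), min_loop = config$min_loop,
                       weights = config$fold_weights)
    sig <- classify_locus(locus, alignments, st, config$thresholds)
    cbind(locus,
          data.frame(total_reads = clusters$n_reads[cl],
                     mature_stack_fraction = sig$mature_stack_fraction,
                     star_stack_fraction = sig$star_stack_fraction,
                     loop_fraction = sig$loop_fraction,
                     end_heterogeneity = sig$end_heterogeneity,
                     classification = sig$classification,
                     reasons = paste(sig$reasons, collapse = ";"),
                     stringsAsFactors = FALSE))
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order_by_locus(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the human-readable summary
#'
#' Echoes the configuration, per-sample read counts at each filter stage,
#' the mapped fraction, candidate counts per length window, the top
#' candidates in each ranking and the locus classification tallies, in a
#' deterministic field order.
#'
#' @param results a `screen_results` from [run_pipeline()].
#' @param path output text file.
#' @return `path`, invisibly.
#' @export
write_summary <- function(results, path) {
  cfg <- results$config
  fmt_cand <- function(df, rank_col) {
    df <- df[order(df[[rank_col]]), , drop = FALSE]
    df <- df[seq_len(min(cfg$top_k, nrow(df))), , drop = FALSE]
    sprintf("  %s:%d-%d(%s) len=%d score=%.3f n5=%d n3=%d",
            df$seq_id, df$start, df$end, df$strand, df$length,
            df$structure_score, df$n5, df$n3)
  }
  lines <- c(
    "== mirtron / miRNA absence screen ==",
    "",
    "[parameters]",
    sprintf("core_bounds=%d-%d", cfg$core_bounds[1], cfg$core_bounds[2]),
    sprintf("extended_bounds=%d-%d", cfg$extended_bounds[1],
            cfg$extended_bounds[2]),
    sprintf("buffer=%d", cfg$buffer),
    sprintf("max_mismatches=%d", cfg$max_mismatches),
    sprintf("index_k=%d", cfg$index_k),
    sprintf("adapter=%s", cfg$trim$adapter),
    sprintf("read_len_window=%d-%d", cfg$trim$min_len, cfg$trim$max_len),
    sprintf("min_mean_quality=%g", cfg$trim$min_mean_quality),
    sprintf("seed_criterion=positions 2-7 identical, <=%d mismatches elsewhere",
            cfg$max_rest_mismatches),
    "",
    "[read counts]",
    sprintf("sample %d: raw=%d filtered=%d distinct=%d",
            results$per_sample$sample, results$per_sample$raw,
            results$per_sample$filtered, results$per_sample$collapsed),
    sprintf("mapped_fraction=%.4f", results$mapped_fraction),
    "",
    "[mirtron screen]",
    sprintf("core candidates (%d-%d nt): %d", cfg$core_bounds[1],
            cfg$core_bounds[2], nrow(results$core)),
    sprintf("extended candidates (%d-%d nt): %d", cfg$extended_bounds[1],
            cfg$extended_bounds[2], nrow(results$extended)),
    "top candidates by structure:", fmt_cand(results$core, "rank_structure"),
    "top candidates by reads:", fmt_cand(results$core, "rank_reads"),
    "top candidates combined:", fmt_cand(results$core, "rank_combined"))
  if (!is.null(results$homology)) {
    lines <- c(lines, "",
               "[known-miRNA screen]",
               sprintf("seed-and-arm matches: %d",
                       nrow(results$homology$seed_matches)),
               sprintf("identity hits (>=11 nt): %d",
                       nrow(results$homology$identity_hits)),
               sprintf("identity hits covering the seed: %d",
                       sum(results$homology$identity_hits$covers_seed)))
  }
  lines <- c(lines, "",
             "[locus classification]",
             sprintf("loci examined: %d", nrow(results$loci)),
             sprintf("plausible: %d",
                     sum(results$loci$classification == "plausible")),
             sprintf("atypical: %d",
                     sum(results$loci$classification == "atypical")))
  writeLines(lines, path)
  invisible(path)
}
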