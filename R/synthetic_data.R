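#' Configuration for the synthetic study generator
#'
#' Defines the simulated study: a multi-gene genome whose introns span the
#' screened length spectrum, a minority of introns planted as mirtron-like
#' hairpins with splice-boundary read stacks, intergenic canonical-miRNA-like
#' hairpin loci with mature/star stacks, hairpin-forming decoy introns with
#' no expression, scatter-decoy loci with uniformly spread reads, and
#' background noise (rRNA-like fragments and random degradation products).
#' Every raw read carries the 3' adapter and is truncated to 36 nt,
#' emulating a 36-cycle single-read run. Defaults give 2020 introns in
#' total (2000 unplanted) with 20 planted mirtrons and 20 canonical loci.
#'
#' @param n_genes number of genes.
#' @param exons_per_gene exons per gene (introns per gene is one fewer).
#' @param exon_len_range,intron_len_range,spacer_len_range inclusive nt
#'   ranges for exon, (unplanted) intron and intergenic spacer lengths.
#' @param n_planted_mirtrons planted mirtron introns in the core 50–120 nt
#'   window; `n_extended_mirtrons` planted in the 121–150 nt extension.
#' @param n_planted_canonical intergenic canonical-miRNA-like loci.
#' @param n_scatter_decoys hairpin loci with scattered (non-miRNA-like)
#'   reads.
#' @param n_decoy_structured_introns introns that fold into hairpins but
#'   receive no reads.
#' @param reads_per_expressed_locus Poisson mean of mature-arm reads per
#'   expressed locus; star reads arrive at one fifth of this rate.
#' @param background_read_count total background reads per sample.
#' @param rrna_contaminant_fraction fraction of background reads drawn from
#'   the planted rRNA-like locus.
#' @param sample_specific_fraction fraction of expressed planted loci
#'   expressed in only one of the two samples.
#' @param error_rate per-base substitution error rate in reads.
#' @param read_len raw (untrimmed) read length in nt.
#' @param adapter 3' adapter appended to every insert.
#' @param mirtron_gc GC fraction of planted hairpin stems; GC-rich stems let
#'   the pairing-weight folder separate planted hairpins from random decoys.
#' @param n_scaffolds number of genome scaffolds.
#' @param seed RNG seed governing all randomness.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 505L, exons_per_gene = 5L,
                       exon_len_range = c(70L, 120L),
                       intron_len_range = c(50L, 150L),
                       spacer_len_range = c(120L, 220L),
                       n_planted_mirtrons = 20L, n_extended_mirtrons = 0L,
                       n_planted_canonical = 20L, n_scatter_decoys = 20L,
                       n_decoy_structured_introns = 20L,
                       reads_per_expressed_locus = 20,
                       background_read_count = 2000L,
                       rrna_contaminant_fraction = 0.2,
                       sample_specific_fraction = 0,
                       error_rate = 0.001, read_len = 36L,
                       adapter = "ATCTCGTATGCCGTCTTCTGCTTGT",
                       mirtron_gc = 0.6, n_scaffolds = 5L, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              exons_per_gene = as.integer(exons_per_gene),
              exon_len_range = as.integer(exon_len_range),
              intron_len_range = as.integer(intron_len_range),
              spacer_len_range = as.integer(spacer_len_range),
              n_planted_mirtrons = as.integer(n_planted_mirtrons),
              n_extended_mirtrons = as.integer(n_extended_mirtrons),
              n_planted_canonical = as.integer(n_planted_canonical),
              n_scatter_decoys = as.integer(n_scatter_decoys),
              n_decoy_structured_introns = as.integer(n_decoy_structured_introns),
              reads_per_expressed_locus = reads_per_expressed_locus,
              background_read_count = as.integer(background_read_count),
              rrna_contaminant_fraction = rrna_contaminant_fraction,
              sample_specific_fraction = sample_specific_fraction,
              error_rate = error_rate, read_len = as.integer(read_len),
              adapter = toupper(adapter), mirtron_gc = mirtron_gc,
              n_scaffolds = as.integer(n_scaffolds), seed = as.integer(seed))
  stopifnot(cfg$n_genes >= 0, cfg$exons_per_gene >= 1,
            cfg$rrna_contaminant_fraction >= 0,
            cfg$rrna_contaminant_fraction <= 1,
            cfg$sample_specific_fraction >= 0,
            cfg$sample_specific_fraction <= 1,
            cfg$intron_len_range[1] >= 10)
  n_slots <- cfg$n_genes * (cfg$exons_per_gene - 1L)
  n_planted <- cfg$n_planted_mirtrons + cfg$n_extended_mirtrons +
    cfg$n_decoy_structured_introns
  if (n_planted > n_slots) {
    stop("config infeasible: ", n_planted, " planted/structured introns but ",
         "only ", n_slots, " intron slots")
  }
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# A hairpin-forming DNA sequence of total length L (transcript orientation):
# stem + loop + revcomp(stem) + 2-nt 3' overhang. Returns the sequence and
# the transcript-relative mature (5' arm start) and star arm intervals for a
# 22-nt duplex with the canonical 2-nt 3' overhang geometry.
build_hairpin_seq <- function(L, gc, arm_len = 22L) {
  k <- (L - 2L - 4L) %/% 2L          # stem with a 4-5 nt loop
  loop <- L - 2L - 2L * k
  stopifnot(k >= arm_len, loop >= 3L)
  stem <- rand_dna(k, gc)
  seq <- paste0(stem, rand_dna(loop, 0.2), revcomp(stem), rand_dna(2L, 0.5))
  # transcript-position partner of stem base p is 2k + loop + 1 - p;
  # star 5' end = partner(mature_end - 2), star spans arm_len nt and ends
  # 2 nt past the partner of the mature start (the 3' overhang)
  mature <- c(1L, arm_len)
  star5 <- (2L * k + loop + 1L) - (arm_len - 2L)
  star <- c(star5, star5 + arm_len - 1L)
  list(seq = seq, mature = mature, star = star)
}

# transcript-relative interval -> genomic interval within [gstart, gend]
rel_to_genomic <- function(rel, gstart, gend, strand) {
  if (strand == "+") c(gstart + rel[1] - 1L, gstart + rel[2] - 1L)
  else c(gend - rel[2] + 1L, gend - rel[1] + 1L)
}

#' Generate a synthetic genome, annotation and planted-truth ledger
#'
#' Deterministic given `config$seed`. Genes are laid out left to right on
#' each scaffold with intergenic spacers; planted loci occupy randomly
#' chosen intron slots (mirtrons, structured decoys) or spacers (canonical,
#' scatter, rRNA-like). Planted mirtron introns fold as
#' stem/loop/reverse-complement-stem with a 2-nt 3' overhang, their mature
#' arm abutting the donor and their star arm ending at the acceptor, so
#' splice-anchored read counting has ground truth to recover.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory; when given, writes `genome.fa`,
#'   `annotation.gff3` and `truth.tsv` there.
#' @return list of class `sim_genome`: `genome` (named character vector),
#'   `exons` (data.frame), `truth` (data.frame with per-locus kind,
#'   coordinates, arm intervals, expression and sample specificity),
#'   `config`.
#' @export
generate_genome <- function(config = sim_config(), out_dir = NULL) {
  set.seed(config$seed)
  n_introns_per_gene <- config$exons_per_gene - 1L
  n_slots <- config$n_genes * n_introns_per_gene
  slot_kind <- rep("intron", n_slots)
  planted_n <- config$n_planted_mirtrons + config$n_extended_mirtrons +
    config$n_decoy_structured_introns
  if (planted_n > 0) {
    picked <- sample(n_slots, planted_n)
    slot_kind[picked] <- rep(c("mirtron", "mirtron_ext", "decoy_hairpin"),
                             times = c(config$n_planted_mirtrons,
                                       config$n_extended_mirtrons,
                                       config$n_decoy_structured_introns))
  }

  # assign genes and intergenic loci to scaffolds round-robin
  gene_scaffold <- rep(seq_len(config$n_scaffolds),
                       length.out = config$n_genes)
  ig_kinds <- c(rep("canonical", config$n_planted_canonical),
                rep("scatter", config$n_scatter_decoys), "rrna")
  ig_scaffold <- rep(seq_len(config$n_scaffolds), length.out = length(ig_kinds))

  scaffolds <- character(config$n_scaffolds)
  names(scaffolds) <- sprintf("scaffold%02d", seq_len(config$n_scaffolds))
  exon_rows <- list()
  truth_rows <- list()
  slot <- 0L
  spacer <- function() rand_dna(sample(config$spacer_len_range[1]:
                                         config$spacer_len_range[2], 1L))
  add_truth <- function(...) {
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(...,
                                                         stringsAsFactors = FALSE)
  }

  for (sc in seq_len(config$n_scaffolds)) {
    sid <- names(scaffolds)[sc]
    parts <- character(0)
    pos <- 0L  # genomic coordinate of the last base emitted
    emit <- function(s) {
      parts[[length(parts) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    emit(spacer())
    for (g in which(gene_scaffold == sc)) {
      strand <- sample(c("+", "-"), 1L)
      n_ex <- config$exons_per_gene
      exon_lens <- sample(config$exon_len_range[1]:config$exon_len_range[2],
                          n_ex, replace = TRUE)
      gene_start <- pos + 1L
      tx_id <- sprintf("tx%04d", g)
      for (e in seq_len(n_ex)) {
        e_start <- pos + 1L
        emit(rand_dna(exon_lens[e]))
        exon_rows[[length(exon_rows) + 1L]] <- data.frame(
          seq_id = sid, start = e_start, end = pos, strand = strand,
          transcript_id = tx_id, gene_id = sprintf("gene%04d", g),
          stringsAsFactors = FALSE)
        if (e == n_ex) next
        slot <- slot + 1L
        kind <- slot_kind[slot]
        i_start <- pos + 1L
        if (kind %in% c("mirtron", "mirtron_ext", "decoy_hairpin")) {
          L <- if (kind == "mirtron_ext") sample(121:150, 1L) else
            sample(80:118, 1L)
          hp <- build_hairpin_seq(L, config$mirtron_gc)
          gseq <- if (strand == "+") hp$seq else revcomp(hp$seq)
          emit(gseq)
          mat <- rel_to_genomic(hp$mature, i_start, pos, strand)
          str_ <- rel_to_genomic(hp$star, i_start, pos, strand)
          add_truth(kind = ifelse(kind == "decoy_hairpin", "decoy_hairpin",
                                  "mirtron"),
                    extended = (kind == "mirtron_ext"), seq_id = sid,
                    start = i_start, end = pos, strand = strand,
                    mature_start = mat[1], mature_end = mat[2],
                    star_start = str_[1], star_end = str_[2],
                    expression = ifelse(kind == "decoy_hairpin", 0,
                                        config$reads_per_expressed_locus))
        } else {
          L <- sample(config$intron_len_range[1]:config$intron_len_range[2],
                      1L)
          emit(rand_dna(L))
        }
      }
    }
    for (ig in which(ig_scaffold == sc)) {
      emit(spacer())
      kind <- ig_kinds[ig]
      strand <- sample(c("+", "-"), 1L)
      l_start <- pos + 1L
      if (kind == "rrna") {
        emit(rand_dna(1200L))
        add_truth(kind = "rrna", extended = FALSE, seq_id = sid,
                  start = l_start, end = pos, strand = strand,
                  mature_start = NA_integer_, mature_end = NA_integer_,
                  star_start = NA_integer_, star_end = NA_integer_,
                  expression = 0)
      } else {
        hp <- build_hairpin_seq(sample(c(58L, 64L, 70L), 1L), config$mirtron_gc)
        gseq <- if (strand == "+") hp$seq else revcomp(hp$seq)
        emit(gseq)
        mat <- rel_to_genomic(hp$mature, l_start, pos, strand)
        str_ <- rel_to_genomic(hp$star, l_start, pos, strand)
        add_truth(kind = kind, extended = FALSE, seq_id = sid,
                  start = l_start, end = pos, strand = strand,
                  mature_start = mat[1], mature_end = mat[2],
                  star_start = str_[1], star_end = str_[2],
                  expression = config$reads_per_expressed_locus)
      }
    }
    emit(spacer())
    scaffolds[sid] <- paste(parts, collapse = "")
  }

  exons <- do.call(rbind, exon_rows)
  truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(kind = character(), extended = logical(), seq_id = character(),
               start = integer(), end = integer(), strand = character(),
               mature_start = integer(), mature_end = integer(),
               star_start = integer(), star_end = integer(),
               expression = numeric(), stringsAsFactors = FALSE)
  if (nrow(truth)) {
    truth$locus_id <- sprintf("locus%03d", seq_len(nrow(truth)))
    expressed <- truth$expression > 0
    spec <- rep("both", nrow(truth))
    flip <- expressed & runif(nrow(truth)) < config$sample_specific_fraction
    spec[flip] <- sample(c("s1", "s2"), sum(flip), replace = TRUE)
    truth$specificity <- spec
  } else {
    truth$locus_id <- character()
    truth$specificity <- character()
  }
  rownames(truth) <- NULL
  sim <- structure(list(genome = scaffolds, exons = exons, truth = truth,
                        config = config), class = "sim_genome")
  if (!is.null(out_dir)) write_sim_genome(sim, out_dir)
  sim
}

#' Write a simulated genome bundle to disk
#'
#' Emits `genome.fa`, `annotation.gff3` (gene/mRNA/exon features with
#' ID/Parent attributes) and `truth.tsv`.
#'
#' @param sim a `sim_genome` from [generate_genome()].
#' @param out_dir output directory (created if absent).
#' @return named character vector of the paths written, invisibly.
#' @export
write_sim_genome <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(out_dir, "genome.fa")
  gff <- file.path(out_dir, "annotation.gff3")
  tsv <- file.path(out_dir, "truth.tsv")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$genome), fa)
  lines <- "##gff-version 3"
  for (tx in unique(sim$exons$transcript_id)) {
    ex <- sim$exons[sim$exons$transcript_id == tx, , drop = FALSE]
    gid <- ex$gene_id[1]
    span <- c(min(ex$start), max(ex$end))
    lines <- c(lines,
               sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       ex$seq_id[1], span[1], span[2], ex$strand[1], gid),
               sprintf("%s\tsim\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       ex$seq_id[1], span[1], span[2], ex$strand[1], tx, gid),
               sprintf("%s\tsim\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                       ex$seq_id, ex$start, ex$end, ex$strand, tx,
                       seq_len(nrow(ex)), tx))
  }
  writeLines(lines, gff)
  write.table(sim$truth, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(genome = fa, gff = gff, truth = tsv))
}

add_seq_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  vapply(seqs, function(s) {
    n <- nchar(s)
    hit <- which(runif(n) < rate)
    if (!length(hit)) return(s)
    ch <- strsplit(s, "")[[1]]
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, character(1))
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate one sample of raw adapter-bearing reads
#'
#' Expressed loci emit mature-arm reads (counts Poisson at the configured
#' mean, 5' ends within 1 nt of the arm start, lengths 21–23 nt), star-arm
#' reads at one fifth of the mature rate, and rare loop reads; scatter
#' decoys emit uniformly placed reads; background reads come from the
#' rRNA-like locus and random genome positions. Every insert gets the 3'
#' adapter appended and is truncated to the configured raw read length,
#' with Phred+33 qualities (a small fraction of reads is emitted
#' low-quality so the quality filter has work to do).
#'
#' @param sim a `sim_genome` from [generate_genome()].
#' @param sample_id 1 or 2; selects which sample-specific loci express and
#'   decorrelates the RNG stream from the genome seed.
#' @param fastq_path optional path to write a FASTQ file.
#' @return data.frame `read_id`, `sequence`, `qualities`, `count` (raw
#'   reads, one row each); written FASTQ is byte-identical across runs with
#'   the same config.
#' @export
simulate_reads <- function(sim, sample_id = 1L, fastq_path = NULL) {
  config <- sim$config
  set.seed((config$seed * 131L + as.integer(sample_id) * 7919L) %% 2147483647L)
  truth <- sim$truth
  inserts <- character(0)

  locus_seq <- function(row) {
    s <- substr(sim$genome[[row$seq_id]], row$start, row$end)
    if (row$strand == "-") s <- revcomp(s)
    s
  }
  emit_stack <- function(lt, rel_start, n, jitter = 1L, len_range = 21:23) {
    if (n <= 0) return(character(0))
    L <- nchar(lt)
    starts <- rel_start + sample(seq(-jitter, jitter), n, replace = TRUE,
                                 prob = if (jitter == 1L) c(0.2, 0.6, 0.2)
                                 else NULL)
    lens <- sample(len_range, n, replace = TRUE)
    starts <- pmax(1L, starts)
    ends <- pmin(L, starts + lens - 1L)
    substring(lt, starts, ends)
  }

  emitted <- data.frame(locus_id = truth$locus_id,
                        n_mature = 0L, n_star = 0L, n_other = 0L,
                        stringsAsFactors = FALSE)
  for (r in seq_len(nrow(truth))) {
    row <- truth[r, ]
    if (row$expression <= 0) next
    if (!(row$specificity %in% c("both", paste0("s", sample_id)))) next
    lt <- locus_seq(row)
    L <- nchar(lt)
    if (row$kind %in% c("mirtron", "canonical")) {
      rel_m <- if (row$strand == "+") row$mature_start - row$start + 1L else
        row$end - row$mature_end + 1L
      rel_s <- if (row$strand == "+") row$star_start - row$start + 1L else
        row$end - row$star_end + 1L
      n_m <- rpois(1L, row$expression)
      n_s <- rpois(1L, row$expression / 5)
      n_l <- rpois(1L, 0.3)
      emitted$n_mature[r] <- n_m
      emitted$n_star[r] <- n_s
      emitted$n_other[r] <- n_l
      inserts <- c(inserts,
                   emit_stack(lt, rel_m, n_m),
                   emit_stack(lt, rel_s, n_s),
                   emit_stack(lt, max(1L, rel_m + 24L), n_l))
    } else if (row$kind == "scatter") {
      n <- rpois(1L, row$expression)
      emitted$n_other[r] <- n
      if (n > 0) {
        lens <- sample(19:24, n, replace = TRUE)
        starts <- vapply(lens, function(l) sample(max(1L, L - l + 1L), 1L),
                         integer(1))
        inserts <- c(inserts, substring(lt, starts, starts + lens - 1L))
      }
    }
  }

  n_bg <- config$background_read_count
  n_rrna <- round(n_bg * config$rrna_contaminant_fraction)
  rrna_row <- truth[truth$kind == "rrna", , drop = FALSE]
  if (nrow(rrna_row) > 0 && n_rrna > 0) {
    lt <- locus_seq(rrna_row[1, ])
    lens <- sample(18:26, n_rrna, replace = TRUE)
    starts <- vapply(lens, function(l) sample(nchar(lt) - l + 1L, 1L),
                     integer(1))
    inserts <- c(inserts, substring(lt, starts, starts + lens - 1L))
  }
  n_rand <- n_bg - n_rrna
  if (n_rand > 0) {
    sids <- sample(names(sim$genome), n_rand, replace = TRUE,
                   prob = nchar(sim$genome))
    lens <- sample(16:28, n_rand, replace = TRUE)
    starts <- vapply(seq_len(n_rand), function(i) {
      sample(nchar(sim$genome[[sids[i]]]) - lens[i] + 1L, 1L)
    }, integer(1))
    frags <- substring(sim$genome[sids], starts, starts + lens - 1L)
    flip <- runif(n_rand) < 0.5
    frags[flip] <- revcomp(frags[flip])
    inserts <- c(inserts, unname(frags))
  }

  inserts <- add_seq_errors(inserts, config$error_rate)
  raw <- substr(paste0(inserts, config$adapter, config$adapter), 1L,
                config$read_len)
  ord <- sample(length(raw))  # shuffle so file order carries no truth signal
  raw <- raw[ord]
  low_q <- runif(length(raw)) < 0.01
  quals <- vapply(seq_along(raw), function(i) {
    n <- nchar(raw[i])
    q <- if (low_q[i]) sample(2:15, n, replace = TRUE) else
      sample(30:40, n, replace = TRUE)
    intToUtf8(q + 33L)
  }, character(1))
  reads <- data.frame(
    read_id = sprintf("sim%d_%06d", sample_id, seq_along(raw)),
    sequence = raw, qualities = quals, count = 1L, stringsAsFactors = FALSE)
  attr(reads, "locus_read_counts") <- emitted
  if (!is.null(fastq_path)) {
    qs <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id)),
      Biostrings::PhredQuality(reads$qualities))
    Biostrings::writeQualityScaledXStringSet(qs, fastq_path)
  }
  reads
}

#' Generate the paired two-sample read set of the simulated study
#'
#' Two read sets drawn from the same planted truth with independent
#' sampling noise; loci flagged sample-specific (see
#' `sample_specific_fraction` in [sim_config()]) express in only one
#' sample, exercising the cross-sample consensus filter.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory for `genome.fa`, `annotation.gff3`,
#'   `truth.tsv`, `sample1.fastq`, `sample2.fastq`.
#' @return list: `sim` (the `sim_genome`), `reads1`, `reads2`.
#' @export
generate_two_samples <- function(config = sim_config(), out_dir = NULL) {
  sim <- generate_genome(config, out_dir = out_dir)
  fq1 <- if (is.null(out_dir)) NULL else file.path(out_dir, "sample1.fastq")
  fq2 <- if (is.null(out_dir)) NULL else file.path(out_dir, "sample2.fastq")
  list(sim = sim, reads1 = simulate_reads(sim, 1L, fq1),
       reads2 = simulate_reads(sim, 2L, fq2))
}
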