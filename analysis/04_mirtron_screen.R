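#!/usr/bin/env Rscript
# Stage 4: the mirtron screen. Derives introns from the gene models, folds
# every candidate in the core (50-120 nt) and extended (121-150 nt) length
# windows, counts splice-site-anchored reads (3-nt buffer, correct
# orientation) and produces the three rankings: by structure score, by
# anchored reads, and combined (sum of ranks).
# Inputs:  results/data/{genome.fa, annotation.gff3}, results/alignments.tsv
# Outputs: results/mirtron_core.tsv, results/mirtron_extended.tsv,
#          results/mirtron_top.bed

library(mirtronscreen)

genome <- read_genome("results/data/genome.fa")
introns <- attach_sequence(derive_introns(read_exons(
  "results/data/annotation.gff3")), genome)
aln <- read.delim("results/alignments.tsv", colClasses = c(
  read = "character", seq_id = "character", strand = "character"))

core <- mirtron_screen(introns, aln, bounds = c(50, 120))
ext <- extended_length_screen(introns, aln, bounds = c(121, 150))
write_screen_report(core, "results/mirtron_core.tsv",
                    top_bed = "results/mirtron_top.bed", k = 5)
write_screen_report(ext, "results/mirtron_extended.tsv")

cat(sprintf("core window candidates: %d; extended window: %d\n",
            nrow(core), nrow(ext)))
top <- core[order(core$rank_combined)[1:5],
            c("seq_id", "start", "end", "strand", "length",
              "structure_score", "n5", "n3")]
cat("top five candidates, combined ranking:\n")
print(top, row.names = FALSE, digits = 3)

# how do they compare against the planted truth?
truth <- read.delim("results/data/truth.tsv")
mt <- truth[truth$kind == "mirtron", ]
key <- paste(core$seq_id, core$start, core$end)
hit <- key %in% paste(mt$seq_id, mt$start, mt$end)
cat(sprintf("planted mirtrons among the top-%d combined: %d/%d\n",
            nrow(mt), sum(hit & core$rank_combined <= nrow(mt)), nrow(mt)))
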