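#!/usr/bin/env Rscript
# Stage 3: map the pooled collapsed reads to the genome on both strands,
# allowing up to two mismatches, and export all alignments.
# Inputs:  results/data/genome.fa, results/collapsed_s{1,2}.tsv
# Outputs: results/alignments.tsv, results/alignments.bed

library(mirtronscreen)

genome <- read_genome("results/data/genome.fa")
pooled <- collapse_reads(do.call(rbind, lapply(1:2, function(s) {
  read.delim(sprintf("results/collapsed_s%d.tsv", s),
             colClasses = c("character", "integer"))
})))
index <- build_index(genome, k = 6)
aln <- map_reads(pooled, index, genome, max_mismatches = 2)
write_alignments(aln, "results/alignments.tsv", "results/alignments.bed")

mapped <- sum(pooled$count[pooled$sequence %in% unique(aln$read)])
cat(sprintf("%d distinct reads (%d raw), %d alignments\n",
            nrow(pooled), sum(pooled$count), nrow(aln)))
cat(sprintf("mapped fraction (raw reads): %.3f\n",
            mapped / sum(pooled$count)))
cat(sprintf("multi-mapping alignments: %d\n", sum(aln$n_hits > 1)))
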