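#!/usr/bin/env Rscript
# Stage 6: locus-signature classification and the cross-sample consensus
# filter. Read clusters are folded and judged against miRNA-annotation
# signature criteria (mature stack dominance, tight 5' ends, few loop
# reads, Dicer-consistent star register); per-sample expressed loci are
# intersected across the two samples. Ends with the summary a reader uses
# to conclude presence or absence.
# Inputs:  results/data/*, results/collapsed_s{1,2}.tsv,
#          results/alignments.tsv
# Outputs: results/locus_signatures.tsv, results/consensus_loci.tsv,
#          results/summary.txt (via the full pipeline for reconciliation)

library(mirtronscreen)

genome <- read_genome("results/data/genome.fa")
aln <- read.delim("results/alignments.tsv", colClasses = c(
  read = "character", seq_id = "character", strand = "character"))
rc <- run_config(genome_fasta = "results/data/genome.fa",
                 gff = "results/data/annotation.gff3",
                 fastqs = sprintf("results/data/sample%d.fastq", 1:2),
                 matures_fasta = "results/known_matures.fa",
                 out_dir = "results/pipeline")

loci <- classify_read_clusters(genome, aln, rc)
write.table(loci, "results/locus_signatures.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("classified %d loci: %d plausible, %d atypical\n", nrow(loci),
            sum(loci$classification == "plausible"),
            sum(loci$classification == "atypical")))

# per-sample expressed loci -> consensus across the two samples
index <- build_index(genome, k = 6)
per_sample <- lapply(1:2, function(s) {
  collapsed <- read.delim(sprintf("results/collapsed_s%d.tsv", s),
                          colClasses = c("character", "integer"))
  collapsed <- collapse_reads(collapsed)
  cluster_alignments(map_reads(collapsed, index, genome), min_reads = 1,
                     method = "stack")
})
cons <- consensus_filter(per_sample)
write.table(cons, "results/consensus_loci.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("loci expressed in both samples: %d (of %d and %d per sample)\n",
            nrow(cons), nrow(per_sample[[1]]), nrow(per_sample[[2]])))

# the full pipeline run writes the reconciled summary report
res <- run_pipeline(rc)
cat("\n", readLines("results/pipeline/summary.txt"), sep = "\n")
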