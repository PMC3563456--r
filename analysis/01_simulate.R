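#!/usr/bin/env Rscript
# Stage 1: generate the simulated study — a multi-gene genome with planted
# mirtron introns, canonical-miRNA-like loci, hairpin and scatter decoys,
# and two samples of raw 36-nt adapter-bearing reads.
# Outputs: results/data/{genome.fa, annotation.gff3, truth.tsv,
#          sample1.fastq, sample2.fastq}

library(mirtronscreen)

cfg <- sim_config(seed = 1)
bundle <- generate_two_samples(cfg, out_dir = "results/data")

truth <- bundle$sim$truth
cat("genome:", length(bundle$sim$genome), "scaffolds,",
    sum(nchar(bundle$sim$genome)), "nt\n")
cat("annotated introns:",
    nrow(derive_introns(bundle$sim$exons)), "\n")
cat("planted loci by kind:\n")
print(table(truth$kind))
cat("raw reads: sample1 =", nrow(bundle$reads1),
    ", sample2 =", nrow(bundle$reads2), "\n")
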