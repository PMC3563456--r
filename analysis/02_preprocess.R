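#!/usr/bin/env Rscript
# Stage 2: adapter trimming, quality/length filtering and collapsing of the
# raw reads, per sample.
# Inputs:  results/data/sample{1,2}.fastq
# Outputs: results/collapsed_s{1,2}.tsv (+ .fa), results/preprocess_counts.tsv

library(mirtronscreen)

params <- trim_params()
counts <- list()
for (s in 1:2) {
  raw <- read_fastq_reads(sprintf("results/data/sample%d.fastq", s))
  trimmed <- trim_adapter(raw, params)
  filtered <- quality_length_filter(trimmed, params)
  collapsed <- collapse_reads(filtered)
  write_collapsed(collapsed,
                  fasta_path = sprintf("results/collapsed_s%d.fa", s),
                  tsv_path = sprintf("results/collapsed_s%d.tsv", s))
  counts[[s]] <- data.frame(sample = s, raw = nrow(raw),
                            filtered = nrow(filtered),
                            distinct = nrow(collapsed))
  cat(sprintf("sample %d: %d raw -> %d after filtering -> %d distinct\n",
              s, nrow(raw), nrow(filtered), nrow(collapsed)))
}
counts <- do.call(rbind, counts)
write.table(counts, "results/preprocess_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
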