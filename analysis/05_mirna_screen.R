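#!/usr/bin/env Rscript
# Stage 5: screen for conserved canonical miRNAs. Abundant reads are matched
# against known matures under the seed-and-arm criterion (identical seed at
# positions 2-7, at most three mismatches in the rest of the arm), and the
# genome is scanned for identity runs to miR-100 and miR-2022 — the two
# miRNAs with claimed conservation outside Bilateria — recording whether
# each run covers the expected seed site.
# Inputs:  results/data/genome.fa, results/collapsed_s{1,2}.tsv
# Outputs: results/known_matures.fa, results/seed_matches.tsv,
#          results/identity_hits.tsv

library(mirtronscreen)

matures <- data.frame(
  name = c("miR-100", "miR-2022"),
  sequence = c("ACCCGUAGAUCCGAACUUGUG", "UUUGCUAGUUGCUUUUGUCCC"),
  stringsAsFactors = FALSE)
writeLines(as.vector(rbind(paste0(">", matures$name), matures$sequence)),
           "results/known_matures.fa")
knowns <- read_matures("results/known_matures.fa")

genome <- read_genome("results/data/genome.fa")
pooled <- collapse_reads(do.call(rbind, lapply(1:2, function(s) {
  read.delim(sprintf("results/collapsed_s%d.tsv", s),
             colClasses = c("character", "integer"))
})))
abundant <- dna_to_rna(pooled$sequence[pooled$count >= 2])

sm <- screen_known_mirnas(abundant, knowns)
write.table(sm, "results/seed_matches.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d abundant reads screened against %d known matures: %d matches\n",
            length(abundant), nrow(knowns), nrow(sm)))

hits <- do.call(rbind, lapply(seq_len(nrow(knowns)), function(i) {
  scan_identity(genome, knowns[i, ])
}))
if (is.null(hits)) hits <- scan_identity(genome, knowns[1, ])[0, ]
write.table(hits, "results/identity_hits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
for (q in knowns$name) {
  h <- hits[hits$query == q, ]
  if (nrow(h) == 0) {
    cat(sprintf("%s: no identity run of 11 nt or more\n", q))
  } else {
    cat(sprintf("%s: longest identity run %d nt, covering the seed: %s\n",
                q, max(h$run_length), any(h$covers_seed & h$run_length ==
                                            max(h$run_length))))
  }
}
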