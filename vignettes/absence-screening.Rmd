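---
title: "Screening a genome for mirtrons and conserved canonical miRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening a genome for mirtrons and conserved canonical miRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirtronscreen)
```

## The problem

Establishing that a genome *lacks* microRNAs is harder than finding them:
every negative must be defensible against the objection that the search was
not sensitive enough. For an early-branching animal whose small RNA
repertoire is in question, three independent lines of evidence are needed:

1. **Mirtron screen.** Mirtrons are short introns that, once spliced, fold
   directly into a pre-miRNA hairpin, bypassing the nuclear Microprocessor
   (Drosha/Pasha). A genome without Drosha could still make mirtrons, so
   every intron in the mirtron length range must be folded and checked for
   small RNA reads stacking precisely at its splice sites.
2. **Conservation screen.** Deeply conserved miRNAs (the only ones with
   claimed conservation outside Bilateria are miR-100 and miR-2022) can be
   searched for directly, by seed-match homology against known matures and
   by identity-run scanning of the genome.
3. **Read-signature classification.** Any locus that does attract reads can
   be judged against the community's annotation criteria for miRNAs: a
   dominant mature stack with sharp 5' ends, few loop-derived reads, and a
   star stack sitting at the duplex position Dicer processing implies.

This package implements all three screens over standard inputs (genome
FASTA, GFF3 gene models, raw small RNA FASTQ, mature-miRNA FASTA), together
with a synthetic-data generator that plants known mirtrons and canonical
loci in a toy genome so that every stage of the pipeline can be validated
by recovery of planted truth, without any external download.

## The mirtron screen

Introns are derived per transcript from exon gaps, de-duplicated across
isoforms on (sequence, start, end, strand), and filtered to the core window
of 50–120 nt, with a separate extension window of 121–150 nt for lineages
whose hairpins run long. Both bounds are inclusive, so the windows are
disjoint. Coordinates are 1-based inclusive throughout; BED exports convert
to 0-based half-open.

### Folding

Each candidate is folded with a maximum-weight nested-pairing dynamic
program (`fold_hairpin()`). For a sequence $s_1 \dots s_n$, the score of
interval $[i, j]$ satisfies

$$
M_{i,j} = \max\Big( M_{i+1,j},\;
  \max_{k:\, k > i + \ell_{\min}} \big\{ w(s_i, s_k) + M_{i+1,k-1} + M_{k+1,j} \big\} \Big)
$$

with pair weights $w(\mathrm{GC}) = 3$, $w(\mathrm{AU}) = 2$,
$w(\mathrm{GU}) = 1$ and minimum loop $\ell_{\min} = 3$. The weights order
the pair classes by duplex stability; they are not free energies, and no
claim of thermodynamic accuracy is made. The traceback is deterministic
(the leftmost base is paired whenever a maximal structure allows it, to its
nearest admissible partner), so all outputs are bit-stable. An exhaustive
enumeration oracle (`brute_force_fold()`, guarded to 14 nt) certifies the
DP exactly in the test suite.

Two numerical points worth knowing:

* The fold score is invariant under reverse complement only for
  Watson–Crick weight schemes. A G·U wobble pair maps to A·C under reverse
  complement, which cannot pair, so with the default weights the two
  orientations of a sequence can differ by a few wobble units. The
  invariance is therefore tested with $w(\mathrm{GU}) = 0$.
* Candidates containing N are excluded from folding (undefined pairing)
  but retained through intron extraction.

### Structure score

The hairpin features (stem length of the longest duplex region, terminal
loop length, paired fraction, 5'/3' overhangs, bulge count) feed a fixed
logistic score

$$
\mathrm{score} = \sigma\big({-6} + 0.25\,\mathrm{stem} + 6\,\mathrm{pf}
  - 0.4\,\mathrm{loop\_pen} - 0.5\,\mathrm{bulges}
  - 0.3\,\mathrm{overhang\_excess}\big)
$$

where `loop_pen` measures the distance of the loop from the preferred
4–20 nt window and `overhang_excess` counts overhang bases beyond the 2 nt
expected of a spliced pre-miRNA. The coefficients were fixed once, by
design: a pairless candidate scores below 0.05, a textbook 30-bp stem with
a 6-nt loop and a 2-nt 3' overhang scores above 0.9, and the score is
strictly monotone in stem length and paired fraction. This is a
transparent, documented stand-in for published SVM-based mirtron scores
(which depend on training data not available here); its role is to order
candidates, and all thresholds live in `mirtron_score_weights()`.

### Splice-anchored read counting

A read supports the 5' splice site of an intron when it maps in the
correct orientation (read strand equal to intron strand — mirtron small
RNAs derive from the sense spliced intron) and its transcript-orientation
5' end falls within ±3 nt of the donor; analogously the read's 3' end for
the acceptor. The buffer and the orientation rule are configurable; the
read terminus is anchored to the site it biologically coincides with
(mirtron hairpin ends are created by splicing). Counts are reported as raw
read tallies (summing collapsed multiplicities), distinct-sequence
tallies, and unique-mapper tallies side by side, because multi-mapping
policy is a genuine degree of freedom: here every alignment of a
multi-mapped read carries its full count, never a fractional weight.

### The three rankings

Candidates are ranked by descending structure score, by descending
splice-anchored read total, and by the ascending **sum** of those two
ranks. The sum-of-ranks form is the package's reading of an
"intersection" ranking: it is total, symmetric in the two criteria, and
only candidates good on both axes reach the top. All ties break on
(sequence, start), making each ranking a deterministic permutation.

## The conservation screen

The seed criterion: a candidate matches a known mature when positions 2–7
are identical and the remaining compared positions carry at most three
mismatches; U and T are equivalent; sequences of unequal length are
compared over the shorter, uncounted 3' overhang allowed. `scan_identity()`
replaces a BLASTN search with what that search is actually used to
measure here: the longest contiguous identity run between query and genome
at every site on both strands (exact word hits of 11 nt extended
maximally), annotated with whether the run covers the query's seed
(positions 2–7). Word floor 11 keeps the scan exact and fast at desk
scale.

The cross-sample consensus filter retains only loci expressed (at least
one read) in every sample, with same-strand interval overlap defining
"the same locus", and ranks retained loci by the number of distinct
supporting methods (union over samples), a designated primary method
breaking ties.

## Read-signature classification

`classify_locus()` projects same-strand alignments into locus coordinates,
partitions the folded hairpin into 5' arm, terminal loop and 3' arm, and
applies four criteria (thresholds in `signature_thresholds()`):

* mature stack fraction ≥ 0.5 of locus reads on the arm holding the modal
  5' end;
* 5'-end heterogeneity (count-weighted mean absolute displacement from the
  modal 5' end) ≤ 2 nt;
* loop-read fraction ≤ 0.1;
* star reads, when present, stacking within 3 nt of the duplex partner of
  (mature 3' end − 2) — the register implied by Dicer's 2-nt 3' overhangs.

A locus failing any criterion is `atypical`, with the failing criteria
listed; a locus with no reads is atypical with reason "no expression".
These thresholds express the community annotation criteria as explicit
numbers; they are deliberately config-exposed because the literature
states them qualitatively.

## The synthetic study

`sim_config()` defines the simulated study conditions; they are fixed
defaults, not tuning knobs:

* ~505 genes × 4 introns gives 2020 introns, of which 20 are planted
  mirtrons (stem–loop–stem hairpins with a 2-nt 3' overhang, mature arm
  abutting the donor, star arm ending at the acceptor), 20 are
  hairpin-forming decoys with no expression, and the rest are random
  sequence with lengths uniform on 50–150 nt (covering both screen
  windows; the empirical intron length spectrum of any particular genome
  is not reproduced at this scale);
* 20 intergenic canonical-miRNA-like loci with mature/star stacks, 20
  scatter decoys (hairpins with uniformly spread reads), and one
  1.2-kb rRNA-like contaminant locus;
* per-locus mature read counts are Poisson with mean 20, star reads at a
  fifth of that rate, rare loop reads; read 5' ends jitter within ±1 nt;
* two samples are drawn independently from the same truth, with a
  configurable fraction of loci expressed in only one sample;
* every raw read is the insert plus the 3' adapter, truncated to 36 nt,
  with Phred+33 qualities and a 1% low-quality read fraction, plus a
  uniform per-base error rate of 0.001.

Planted stems are 60% GC so that the pairing-weight folder separates
planted hairpins from random decoys — a simulation choice, not a
biological claim. Everything is deterministic given the seed; sample
streams are decorrelated by hashing the seed with the sample number.

What the generator does *not* emulate: realistic quality-score decay,
indel errors, expression heterogeneity across loci, isoform complexity,
and unmappable contaminants (so simulated mapping rates are near 1 and
are not comparable to real libraries). Passing the recovery tests shows
the pipeline's logic is sound, not that real genomes behave this simply.

## Problem sizes and verification

The package's own verification, all run by the test suite and
`scripts/acceptance.R`:

* folding DP vs exhaustive enumeration, 200 random sequences of 8–14 nt
  across several weight schemes;
* seeded mapper vs brute-force Hamming scan, 200 random read/genome pairs
  (genomes to 10 kb, reads 18–26 nt, 0–2 mismatches), with exact
  alignment-set identity;
* the seed-and-arm rule on an exhaustive grid of mismatch placements;
* five independent full-scale simulated studies (2020 introns each) for
  planted-mirtron recovery, decoy false-positive control, and
  canonical/scatter classification rates;
* consensus-filter behaviour under 50% sample-specific expression, and
  byte-level determinism of all artifacts under a fixed seed.

These sizes keep the whole surface within a few minutes on one CPU while
leaving no stage untested at the scale its statistics need.

## Known limitations

* The folder is a weighted base-pairing DP, not a thermodynamic model;
  scores order candidates but do not estimate free energies. An external
  thermodynamic folder can be substituted for cross-checks via the
  `fold_weights`/`min_loop` plumbing without changing any downstream code.
* The mapper is substitution-only by design (short reads, exact oracle);
  indel alignments are out of scope.
* The structure score's coefficients are fixed by designed anchors, not
  trained; on real data its absolute values should not be compared across
  species, only used as a ranking.
* Intron de-duplication collapses isoform-shared introns; annotation
  pipelines that count transcript-intron incidences will report different
  candidate totals.
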