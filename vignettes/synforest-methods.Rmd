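---
title: "Methods: classifying deleterious synonymous variants with synforest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifying deleterious synonymous variants with synforest}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Synonymous single-nucleotide variants (sSNVs) preserve the protein sequence
but can be pathogenic through splicing disruption, loss of exonic splicing
enhancers (ESEs), altered codon optimality and translation efficiency, or
damage to overlapping regulatory elements. `synforest` frames their
classification as supervised binary learning: each variant is represented by
a feature vector spanning splicing geometry, motif content, codon usage,
translation efficiency, conservation and functional-region annotation, and a
random forest outputs the probability that the variant is deleterious — the
fraction of trees voting for the deleterious class.

The pipeline, in order:

1. **Projection.** A variant is assigned its canonical transcript — the one
   with the longest CDS among those whose CDS contains it, ties broken by
   lexicographically smallest transcript id — and projected into codon space
   on the coding strand. Variants whose reference and alternate codons
   translate identically under the standard genetic code (stop-to-stop
   included) are synonymous; all others are rejected from assembly with a
   report. Only the standard nuclear code is supported.
2. **Feature extraction** (below) into a variants × features matrix with an
   explicit missing mask.
3. **Imputation and normalisation.** Missing cells are set to zero on the
   raw scale *first*, then every feature is z-scored, `(x - mean) / sd`,
   with the sample (n−1) standard deviation. Parameters are fitted on
   training rows only and frozen for any held-out data: pooling test rows
   into the normalisation would leak information, so the conservative
   train-only convention is used. Zero-variance features normalise to zero.
4. **Model construction.** A seeded random forest (the `randomForest`
   engine; default `ntree = 500`, `mtry = 3`). Hyperparameters can be tuned
   by grid search over `ntree ∈ {50, 100, …, 1000}` × `mtry ∈ {1, …, 10}` —
   200 configurations — under the cross-validated AUC criterion; ties go to
   the smaller `ntree`, then the smaller `mtry` (cheaper, simpler models).
5. **Feature selection.** Sequential backward selection (SBS): at each step
   every single-feature removal is scored by stratified 10-fold
   cross-validated AUC on pooled out-of-fold predictions, with the folds
   held fixed across the whole selection; the best removal is accepted when
   the criterion does not decrease (`strict = TRUE` demands improvement),
   with ties broken by removing the lexicographically smallest name.
   Selection stops when every removal strictly hurts, or one feature
   remains. The criterion along accepted steps is therefore non-decreasing.
   The grid search is run once on the full feature set and the resulting
   configuration is held fixed during SBS; re-tuning inside every SBS step
   would multiply cost ~200-fold for marginal benefit.

Cross-validation is stratified by class and seeded; each fold re-fits
imputation and normalisation on its training part, so no fold ever sees
held-out statistics.

## Feature conventions

The geometry features are exposed as documented conventions:

* **DSP** — distance in nt to the nearest splice site of the hosting exon; a
  variant on the boundary base scores 0 (not 1). Exon ends at the transcript
  terminus are not splice sites and are excluded while an internal boundary
  exists; single-exon transcripts yield a missing value (0 after
  imputation).
* **MDE** — DSP divided by half the exon length.
* **DVE** — the 0-based offset from the exon's 5′ end in transcript
  orientation divided by `exon_len − 1` (0 at the 5′-most, 1 at the 3′-most
  base).
* **CpG** — whether either reference dinucleotide containing the position is
  CG on the genome's plus strand.
* **RMP** — `cds_pos / CDS length`.
* **MES** — the maximum, over both splice-site matrices and every window on
  the coding strand overlapping the variant, of the window's summed
  log-odds. The default matrices are synthetic consensus-derived donor
  (width 9, 3 exonic columns) and acceptor (width 23, 3 exonic columns)
  models; they are pluggable, and users with access to matrices estimated
  from real splice-site alignments (maximum-entropy or PWM) should
  substitute them. Full maximum-entropy dependency models are deliberately
  out of scope — the interface (a score that is maximal over
  variant-overlapping windows) is identical.
* **ese_dens** — hexamer-set hits per length-6 window of the hosting exon,
  `hits / (len − 5)`.
* **SR_lost** — motif hits lost between the reference and alternate window,
  an 11-nt window centred on the variant and truncated at exon boundaries —
  wide enough to cover every hexamer overlapping the variant.
* **RSCU / dRSCU** — a codon's count over the mean of its synonymous family;
  single-codon families are fixed at 1, all-zero families at 0, so the
  family sum equals the family size whenever the family is observed.
  `dRSCU = RSCU(alt) − RSCU(ref)`.
* **TE** — the log tRNA-adaptation weight of the *alternate* codon,
  `ln w(alt)`. The adaptation weight of a codon sums `(1 − s) × copies`
  over its decoding anticodons (Watson–Crick plus the configured wobble
  classes; defaults G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68, with
  anticodon A read as inosine), normalised by the maximum; undecoded codons
  receive the geometric mean of the nonzero weights, the usual convention,
  so the logarithm is always finite. Because "the log of the adaptation
  index of the variant codon" admits a second reading — the change relative
  to the reference codon — `te_feature(..., delta = TRUE)` also emits
  `ln w(alt) − ln w(ref)`.

Scores the package does not compute natively (conservation, splicing-change
z-scores, folding energies) are ingested as exact-key TSV extracts —
position-keyed (`contig, pos, score`) or allele-keyed
(`contig, pos, ref, alt, score`), keys as published, no strand
normalisation — and each configured BED track becomes one boolean
overlap column. Absent keys are missing values, hence zero after imputation.

All internal coordinates are 1-based closed, the R/Bioconductor
(IRanges/GRanges) convention; every input format except BED is already
1-based, and BED's 0-based half-open intervals are converted once at parse
time. Multiallelic VCF rows are decomposed and only SNVs kept.

## Evaluation protocol

A variant is called deleterious when its probability is at or above 0.5 (the
threshold is an argument everywhere). Besides AUC — rank-based
(Mann–Whitney), ties credited one half, which equals brute-force
positive-negative pair counting — performance is reported as recall,
precision and the weighted F-measure
`F_beta = (beta² + 1)·P·R / (beta²·P + R)`, with `beta` the
majority-to-minority class ratio rounded to the nearest integer
(`class_ratio_beta(5178, 153) = 34`). Large `beta` makes the measure tend to
the recall, which is the quantity of interest when deleterious variants are
rare; `beta = 1` is the harmonic mean.

Supporting machinery:

* **Gene-matched negatives** — putative benign variants are kept only if
  their gene hosts at least one positive (removing gene-level ascertainment
  bias), and variants identical to training-set entries are discarded.
* **Balanced-subset resampling** — on an imbalanced test set, as many
  negatives as positives are drawn without replacement, freshly per run
  (default 5 runs), and metrics are reported as mean ± sample SD with
  `beta = 1`. The positives are fixed, so recall has zero spread by
  construction. Methods are compared on the *same* subsets with a
  two-tailed paired t-test, paired by run index; all-zero differences give
  p = 1 by convention, constant nonzero differences p = 0.
* **Ablation** — one cross-validated evaluation per left-out feature plus
  the all-features row.
* **Imbalance sweep** — negatives resampled at 10–50× the positive count
  (capped at the pool with a warning), reporting CV and optional held-out
  AUC per multiplier.

## The synthetic generator

Curated pathogenic/benign sSNV collections cannot ship with a package, so
`simulate_dataset()` generates the full input surface: one contig with
multi-exon genes on alternating strands (coding sequences sampled codon-wise
from the sense codons, so no internal stops; donor `GTAAGT` and
pyrimidine-tract acceptor consensus embedded at intron ends), motif, codon
usage and tRNA resources, labelled synonymous variants, and class-shifted
score tables and annotation tracks — all written in the standard formats
(FASTA/GTF/VCF/BED/TSV) when a directory is configured.

Signal is injected **at the feature level** — placement plus simulated
tracks — because no accepted generative model of deleterious sSNVs exists;
this is a testing device emulating the *structure* of curated variant sets,
not biology. The defaults are the study conditions used throughout the
tests: 300 deleterious + 300 benign variants (600 total) over 60 five-exon
genes, a 5% missing rate, and effect sizes chosen once as a clear but not
degenerate signal: deleterious variants fall within 6 nt of an internal
splice site, in ESE-dense exons (the ESE set is harvested from a random half
of the exons), and adopt the least tRNA-adapted synonymous codon; simulated
conservation tables are shifted by 2.0 and 1.2 SD, splicing-change z-scores
by 1.5 SD; annotation-track coverage is 55%/45% for deleterious vs 8%/10%
for benign. The default ten-feature matrix carries nine signal-bearing
columns plus one pure-noise column (`noise`), giving selection something
real to discard. `null_effects()` switches every shift off for calibration:
the cross-validated AUC then sits near 0.5.

What passing tests show — and what they do not: under these conditions the
pipeline recovers the planted signal almost perfectly (CV AUC ≈ 1), because
the simulated effects are independent, stationary and much cleaner than real
annotation. Real sSNV data carry correlated, noisy, incomplete features, and
performance there is an empirical question this generator cannot answer; the
tests demonstrate that the machinery (projection, extraction, imputation,
normalisation, selection, tuning, evaluation) is correct and deterministic,
not that any particular AUC is attainable on real variants.

Problem sizes used by the test suite were chosen to keep a full run in a few
minutes on one CPU: the recovery checks run at the full 600-variant study
conditions (forest of 500 trees for the CV check, 150 for the selection
trace, whose per-step cost is ~100 forest fits); the 200-point grid-search
check runs on a 60-variant fixture; unit tests use 100–120 variants.

## Numerical and design choices

* Deterministic everywhere: fold assignment, forest training, resampling and
  simulation each take explicit seeds; identical seeds give byte-identical
  outputs (a tested property).
* SBS acceptance uses `≥` — removal is allowed while the criterion does not
  decrease — honouring "stop when no removal increases the criterion" while
  still shedding redundant features; a strict-improvement variant is a flag.
* The classification threshold for confusion counts is 0.5.
* `beta` rounds to the nearest integer (5178/153 = 33.84 → 34).
* Canonical-transcript policy (longest CDS, id tie-break) is a documented
  package convention; gene models are user input, and no particular genome
  build or transcript set is assumed.
* Windows for the splice-site scan that would extend past a contig are
  skipped; if none remain, the feature is missing. Windows containing `N`
  are skipped likewise.
* Two published balanced-subset table rows are internally inconsistent with
  their own printed means at three decimals (a harmonic mean of
  0.765/0.781 gives 0.773, of 0.575/0.971 gives 0.722); the worked-example
  tests assert only rows consistent with their own printed
  recall/precision, and these two are noted here instead. The same applies
  to two ablation rows (0.667/0.810 → 0.732; 0.673/0.798 → 0.730).

## Known limitations

* No thermodynamic RNA-folding features (ΔG, ensemble diversity); they enter
  only as precomputed score columns.
* The default splice-site matrices are synthetic consensus models — adequate
  for testing and for relative ref/alt comparisons, not a calibrated
  replacement for matrices estimated from real splice-site alignments.
* One canonical transcript per variant; isoform-aware aggregation is not
  attempted.
* No probability calibration; forest vote fractions are used as-is.
* The generator's independence assumptions overstate real-data separability,
  as discussed above.
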