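# synforest

Feature-based random-forest classification of deleterious synonymous
single-nucleotide variants (sSNVs).

## The problem

Synonymous variants leave the protein sequence unchanged, yet a minority are
pathogenic — typically by disrupting splicing (splice-site motifs, exonic
splicing enhancers), by shifting codon optimality and translation efficiency,
or by damaging regulatory elements. Because deleterious sSNVs are rare,
classifying them is a heavily imbalanced learning problem, and generic
variant-effect predictors are poorly calibrated for it. `synforest` is for
variant-analysis practitioners and method developers who need a transparent,
reproducible sSNV classifier whose every feature and evaluation step can be
inspected, retrained on their own labelled variants, and tested end to end
without external downloads.

## The model

Each synonymous variant is projected onto its canonical transcript (longest
CDS) and represented by a feature vector combining

* **native sequence features** — distance to the nearest splice site (DSP),
  its exon-relative variants (MDE, DVE), CpG context, relative CDS position,
  exonic-splicing-enhancer hexamer density, SR-motif losses, a sliding
  log-odds splice-site matrix score (MES), relative synonymous codon usage
  (RSCU) change, and the translation-efficiency feature
  `TE = ln w(alt codon)` where `w` are tRNA adaptation weights derived from
  anticodon gene-copy numbers with wobble penalties; and
* **ingested genome-track scores** — per-position conservation (e.g. phyloP),
  per-allele splicing-change z-scores (dPSI z), and boolean overlaps with
  annotation tracks (TFBS, histone marks, ...), supplied as TSV/BED extracts.

Missing values are set to zero, features are z-score normalised with
parameters fitted on training rows only, and a random forest
(`ntree = 500`, `mtry = 3` by default) is trained on the result.
Hyperparameters are tuned by grid search over
`ntree ∈ {50, 100, …, 1000} × mtry ∈ {1, …, 10}` (200 configurations) and
features are pruned by sequential backward selection, both under a stratified
10-fold cross-validated AUC criterion.

Evaluation follows the imbalance-aware protocol: besides AUC, performance is
summarised by recall, precision and the weighted F-measure

```
F_beta = (beta^2 + 1) * precision * recall / (beta^2 * precision + recall)
```

with `beta` set to the majority/minority class ratio (e.g. 5178 benign vs 153
deleterious gives `beta = 34`), plus gene-matched negative filtering,
balanced-subset resampling with paired t-tests, leave-one-feature-out
ablation, and a class-imbalance sweep.

## Worked example

The built-in generator simulates a toy genome, gene models, motif/codon/tRNA
resources, score tables and labelled synonymous variants with class signal
injected at the feature level, then assembles the ten-feature default matrix:

```r
library(synforest)
sim <- simulate_dataset(sim_config(seed = 1, n_genes = 20,
                                   n_pos = 60, n_neg = 60))
fit <- synforest(sim$fm, config = rf_config(ntree = 300, mtry = 3, seed = 1),
                 k = 5)
summary(fit, beta = 1)
#> Deleterious-sSNV random forest
#>   120 training variants (60 deleterious / 60 benign), 10 features
#>   ntree = 300, mtry = 3, seed = 1
#>   cross-validated AUC: 0.999
#>   feature importance (mean decrease in Gini):
#>     DSP             25.13
#>     cons            15.74
#>     dPSIZ            6.63
#>     MES              4.87
#>     ese_dens         3.47
#>     gerp             1.38
#>     histone          0.97
#>     TE               0.67
#>     noise            0.36
#>     TFBS             0.26
#>   out-of-fold evaluation: <eval: TP 60 FP 1 TN 59 FN 0 | recall 1.000 precision 0.984 F(beta=1) 0.992 AUC 0.999>
```

The splice-distance and conservation features dominate, the planted
`noise` column ranks at the bottom, and the out-of-fold evaluation reports
the confusion counts with recall/precision/F/AUC. `predict(fit, newdata)`
scores new variants through the frozen pipeline;
`sbs_select()`, `grid_search()`, `ablation_table()`, `imbalance_sweep()` and
`balanced_subset_eval()` expose the selection and evaluation machinery
directly. The evaluation arithmetic is available standalone, e.g.

```r
f_beta(recall = 0.765, precision = 0.098, beta = 34)   # 0.761
class_ratio_beta(5178, 153)                            # 34
```

A command-line interface (installed at `exec/synforest`, or via
`synforest_cli()`) chains the same steps:
`simulate`, `annotate`, `select-features`, `train`, `predict`, `evaluate`.

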