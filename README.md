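# delpath

Pathogenicity prediction for short **sequence-retaining protein deletions** —
in-frame deletions of 1–10 amino acids that remove residues without altering
the downstream protein sequence. Such deletions are common among both
disease-causing and tolerated variants, and a large share of them cannot be
confidently assigned either way. delpath is for variant-interpretation
researchers and method developers: it provides the full training and
evaluation machinery for a gradient-boosted deletion classifier, including a
third output class — **VUS** (variant of uncertain significance) — for
variants on which the model abstains, plus a synthetic-data generator so the
entire pipeline is testable without any external resources.

## The method

Each deletion (protein, 1-based closed interval `[start, end]`, `start > 1`
since removing the initiator residue abolishes translation) is described by
four feature categories:

* **context** — sequence-logo bit scores around the deletion boundary. For
  offsets −5..−1 and +1..+5 relative to the deletion, class-specific logos
  give each residue the score `freq(a, o) · info(o)` with
  `info(o) = log2 20 − H(freq_o)` bits; the up- and downstream sums per class
  logo are the features. Fixed-length 5-residue segments (deletion, upstream,
  downstream) are carried alongside for sequence-aware models.
* **content** — averages over the deleted residues of amino-acid property
  scales (AAindex format supported) and of provider-supplied per-residue
  tracks (conservation, solvent accessibility, substitution pathogenicity).
* **position** — deletion length, relative position, distance to the nearest
  terminus, and 0/1 overlap flags against annotation intervals (domains,
  repeats, transmembrane segments, disordered regions, secondary-structure
  classes, last-exon windows, sequence palindromes found internally).
* **gene** — per-gene class flags (haploinsufficiency, housekeeping, ...),
  gene age, and six interaction-network centralities (degree, closeness,
  betweenness, harmonic, hub score, Bonacich power).

Features pass a three-stage filter fitted on training data (rare binaries
with minority < 6; exact zero variance; greedy removal of any feature with
|Spearman ρ| > 0.8 against an already-kept one). `del_train()` then fits
**25 gradient-boosted models** — five protein-disjoint 5-fold partitions,
one model per (split, fold) — sharing one feature list, optionally after
recursive feature elimination and a seeded random hyperparameter search.

Prediction is two-layered. The binary score is the ensemble mean
probability, thresholded at 0.5. For the three-state output, the 25 member
probabilities are bootstrap-resampled (B = 1000) and tested two-sided
against the no-evidence mean 0.5:

    p = min(1, 2 · min(#{m* ≥ 0.5}, #{m* ≤ 0.5}) / B)

Variants with `p ≥ α` (default α = 0.05) are reported as VUS; the rest are
pathogenic or benign by the mean probability.

Evaluation uses the standard confusion-matrix suite — PPV, NPV, sensitivity,
specificity, accuracy, MCC — plus the composite overall performance measure

    OPM = (PPV + NPV)(Sens + Spec)(Acc + (1 + MCC)/2) / 8

computed on raw and class-normalised counts (benign row scaled so both
classes have equal totals), with VUS counted only as missingness.

## Worked example

Simulate a labeled feature table, hold out a protein-disjoint test set,
filter, fit the 25-model ensemble and classify the held-out variants:

```r
library(delpath)
tab  <- simulate_feature_table(n_rows = 1200, n_features = 30,
                               n_informative = 5, effect = 1.5, seed = 42)
plan <- make_split(tab, test_frac = 0.2, seed = 42)
train <- tab[tab$protein_id %in% plan$train_proteins, ]
test  <- tab[tab$protein_id %in% plan$test_proteins, ]

flt  <- filter_features(train)
fit  <- del_train(flt$table, seed = 42)
fit
#> Deletion-pathogenicity ensemble: 25 models ( 5 splits x 5 folds ), 30 features, learner gbdt

pred <- predict(fit, apply_filter(test, flt$report), type = "tristate", seed = 42)
head(pred, 3)
#>   variant_id  mean_prob p_value       call
#> 1     v00001 0.96752855       0 pathogenic
#> 2     v00005 0.09090253       0     benign
#> 3     v00008 0.09107155       0     benign

evaluate_tristate(test$label, pred$call)
#> PPV          0.95 (0.95)
#> NPV          0.96 (0.96)
#> sensitivity  0.96 (0.96)
#> specificity  0.95 (0.95)
#> accuracy     0.95 (0.95)
#> MCC          0.91 (0.91)
#> OPM          0.87 (0.87)
#> counts       TP 109.0 TN 118.0 FP 6.0 FN 5.0  (norm TN 108.5 FP 5.5)
#> missing      18 (7.0%)
auc_rank(test$label, pred$mean_prob)
#> [1] 0.9744898
```

The ensemble recovers the planted five-feature signal almost perfectly on
held-out proteins and abstains (VUS) on the 7% of variants whose member
probabilities straddle 0.5. On real sequence-level inputs the same flow
starts from `read_fasta()` / `read_variants()` / `featurize()`; a thin
command-line wrapper (`inst/cli/delpath`) exposes `simulate`, `featurize`,
`filter`, `train`, `predict`, `evaluate` and `sweep-alpha` subcommands.

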