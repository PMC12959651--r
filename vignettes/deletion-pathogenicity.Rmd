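---
title: "Modelling the pathogenicity of short sequence-retaining protein deletions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the pathogenicity of short sequence-retaining protein deletions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delpath)
```

## The problem and the model

Short in-frame deletions — up to 10 amino acids, leaving the downstream
sequence intact — occupy an awkward middle ground in variant interpretation:
frequent enough to matter clinically, too heterogeneous for conservation
scores alone, and often reported with uncertain significance. delpath models
the task as supervised binary classification with an explicit abstention
layer on top.

The fitted object is an *ensemble of 25 gradient-boosted decision-tree
classifiers*: the training variants are partitioned five independent times
into five protein-disjoint fold groups, and one model is fitted per
(partition, fold) on the out-of-fold rows. All 25 models share one feature
list. Binary prediction uses the ensemble mean probability against the 0.5
threshold (a mean of exactly 0.5 counts as benign). The three-state layer
asks a different question — *do the 25 models agree that there is evidence
at all?* — by bootstrap-resampling the member probabilities (B = 1000) and
testing their mean two-sided against 0.5; the doubled smaller inclusive tail,
capped at 1, is the p-value. Variants with `p >= alpha` become VUS.

Assumptions worth making explicit:

* *Protein-level exchangeability within a class*: splits and folds are
  stratified by a protein-level class (majority label of the protein's
  variants, ties counted pathogenic), assuming proteins — not variants — are
  the independent sampling units. Variants of one protein never straddle a
  train/test boundary.
* *Member diversity*: the abstention test treats the 25 probabilities as an
  approximately exchangeable sample of "model opinions". Because the models
  share most of their training data, this only holds if the learner itself
  injects enough randomness (see *Why the learner defaults look aggressive*).
* *Raw probabilities*: no recalibration is applied between the learner and
  the 0.5 threshold.

## Features

Four categories are assembled by `featurize()`:

* **context** — per-offset sequence logos (offsets −5..−1, +1..+5 around the
  deletion boundary) built separately from benign and pathogenic training
  variants. Information content is `log2(20)` minus the Shannon entropy of
  the raw frequency column; letter score is frequency times column
  information. A variant's features are the up- and downstream sums of the
  observed residues' scores under each class logo (four non-negative sums),
  plus a signed pathogenic-minus-benign total. Logos are fitted objects:
  they must be built on training variants only, or context features leak
  label information into evaluation data.
* **content** — means over the deleted residues of amino-acid property
  scales and of per-residue numeric annotations. Non-standard residues (X)
  are excluded from numerator and denominator; an all-X deletion makes the
  feature unavailable.
* **position** — length, midpoint/length relative position, distance to the
  nearest terminus, protein length, and closed-interval overlap flags per
  annotation category. Palindromic stretches are found internally (centre
  expansion plus containment filter, default minimum length 5 — configurable,
  as there is no canonical value).
* **gene** — per-protein scalars and six interaction-network centralities
  via igraph. Edge weights are ignored for path-based metrics (interaction
  confidences are similarities, not distances); the hub score is the
  principal eigenvector of the adjacency matrix computed by dense symmetric
  eigendecomposition (deterministic, unlike iterative HITS solvers); power
  centrality uses attenuation 0.9/λ_max, just inside the convergence radius.

Rows with any unavailable feature are excluded and reported ("prediction not
possible") rather than imputed — on real data this mirrors proteins lacking
structural models or evolutionary context.

## Feature filtering

`filter_features()` runs three deterministic stages fitted on training data
and replayed on evaluation data via `apply_filter()`: binary features whose
minority class has five or fewer observations; numeric features with exactly
zero variance (near-zero variance is deliberately left to the next stage);
and a greedy scan in registry order (category, then name) dropping any
numeric feature whose absolute Spearman correlation with an already-kept
feature exceeds 0.8. Keeping the *earlier* column makes the cascade fully
deterministic; the fixed-length sequence segments bypass all stages. The
cascade is idempotent and its output contains no kept pair above the
threshold, both of which are property-tested.

## Training, feature selection, tuning

`make_split()` assigns whole proteins to train/test greedily within class
until the held-out variant count reaches the target fraction, then balances
folds by variant count per class. Cross-validation reports fold-averaged
(hence fractional) confusion counts with metrics computed on the averages,
and the mean fold AUC.

`rfe_select()` ranks features by recursive elimination along the candidate
size grid (default top 10..190 by 10) and picks the *smallest* size whose
mean cross-validated AUC is within `tol = 0.005` of the best — preferring a
compact model over a fraction of a point of AUC. `tune_hyperparams()` is a
seeded uniform random search (100 trials by default) over learning rate,
boosting type (gbtree/dart), leaves, L1/L2, bagging fraction, minimum child
weight, minimum split gain and feature fraction, scored by mean CV AUC with
an incumbent log.

## Why the learner defaults look aggressive

`learner_gbdt()` defaults to 60 rounds at learning rate 0.3 with row
subsampling 0.25 and per-tree feature sampling 0.08. These are *ensemble
member* defaults, chosen for diversity rather than single-model polish: with
conventional boosting settings the 25 members — trained on heavily
overlapping data — produce almost perfectly correlated predictions, and the
bootstrap test degenerates into a sign test that rejects everywhere, so the
VUS layer abstains on almost nothing even when there is no signal at all.
Strong stochastic subsampling makes each member's noise fit its own, which
(a) leaves genuinely uninformative variants with member opinions straddling
0.5, hence VUS, and (b) costs nothing measurable on strongly separable data.
This choice was validated on the synthetic generator across multiple seeds
at both zero and strong effect sizes. Users wanting one maximally sharp
model should run the hyperparameter search and accept that the abstention
layer then behaves more aggressively.

`alpha >= 1` disables abstention entirely and reduces the three-state
predictor *exactly* to the binary one. This is a deliberate special case:
the p-value is capped at 1, so the literal `p >= alpha` rule would still
abstain on degenerate all-0.5 member vectors at alpha = 1, contradicting the
"no uncertainty" reading of that threshold. For `alpha < 1` the rule is
literal. Per-variant bootstrap seeds are derived from a hash of the variant
id plus the global seed, so p-values are independent of batch composition
and order.

## The synthetic generator

Two generators cover different test depths.

`simulate_proteome()`/`simulate_variants()` emulate the *structure* of
curated deletion datasets: Swiss-Prot-like residue composition; domain
intervals covering a configurable fraction (default 0.4) of each protein;
terminus-biased disorder; repeat/transmembrane intervals; an eight-class
secondary-structure partition whose low-confidence class co-locates with
disorder; per-residue conservation, accessibility and substitution
pathogenicity correlated with domain membership; gene-class flags; and a
sparse random interaction graph. Variants default to 57.7% pathogenic with
class-conditional truncated-geometric lengths matching means 2.71
(pathogenic) and 4.11 (benign) — the geometric family is our choice; the
targets pin its mean and both classes keep their mode at length 1. With
positive `effect`, pathogenic deletions concentrate in domains and conserved
positions, benign ones near termini and in disorder; `effect = 0` is an
exact placement null.

`simulate_feature_table()` skips sequences and emits a labeled feature table
directly, with planted informative columns (class means separated by
`effect` standard deviations), optional redundant/constant/rare-binary
columns for filter tests, and rows grouped into proteins so protein-disjoint
splitting is exercised. Its class prior defaults to *balanced* (0.5), unlike
the proteome generator: this generator's job is testing the learning and
abstention machinery, and a balanced prior makes the zero-effect
configuration a true coin-flip null in which ensemble probabilities should
straddle 0.5.

What passing tests on these generators does **not** show: real deletion data
have database-specific label biases (e.g. very few benign records in
locus-specific databases), correlated annotation errors, and feature
distributions far from Gaussian; synthetic results certify the machinery,
not clinical performance.

## Numerical choices and degenerate inputs

* Logo columns use raw frequencies, no small-sample correction; an offset
  with zero observations gets uniform frequencies and information 0.
* MCC with a zero denominator is reported as 0; ratio metrics with a zero
  denominator as 0 with a warning; OPM is the product form divided by 8,
  verified against every recomputable printed value of the benchmark tables.
* Class normalisation scales the *benign* row by (TP+FN)/(TN+FP) — the
  direction consistent with published normalised counts; all ratio metrics
  are provably invariant to which row is scaled (property-tested), so the
  direction affects displayed counts only.
* Display rounding is two decimals; everything internal is full precision.
* Bootstrap p-values sort the member vector first, making them exactly
  permutation-invariant.
* Duplicate variants collapse on (protein, start, end); duplicates with
  conflicting labels are dropped entirely with a warning — the conservative
  reading where sources disagree.
* Coordinates are 1-based closed intervals everywhere; interval adjacency is
  not overlap. Genomic coordinates are never parsed — pre-map nucleotide
  deletions to protein coordinates (TransVar/VEP) upstream.

## Problem sizes used in the shipped tests

The test suite validates the full pipeline at 2,000 variants x 50 features
(5 informative) for both the strong-signal and null regimes, the filtering
cascade at 611 planted features on 500 rows, the sequence-level end-to-end
path at 60 proteins / 400 variants, and the oracle equivalences (palindromes,
interval overlap, AUC, centralities) at brute-force-tractable sizes. These
sizes were chosen to make the statistical assertions stable under the fixed
seeds while keeping the suite quick to run.

## Known limitations

* External annotations (conservation, structure-derived accessibility,
  domain calls, gene classifications, interaction networks) are consumed as
  provider tables, never recomputed; prediction is impossible for proteins
  the providers do not cover.
* The blind-test discipline is the caller's: `del_train()` treats everything
  it receives as training material. Hold out proteins first with
  `make_split()`.
* No probability recalibration or conformal abstention; the VUS layer is a
  bootstrap sign-level test and inherits its conservatism.
* Deletions longer than 10 residues, frameshifts and first-position
  deletions are out of scope by construction.
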