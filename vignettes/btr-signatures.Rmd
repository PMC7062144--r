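---
title: "Sparse BTR signature models for microbiome data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse BTR signature models for microbiome data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model family

`btrsign` learns sparse decision rules on feature abundance tables
(taxa, genes or pathways in rows, samples in columns). A rule is a linear
score with coefficients restricted to a discrete alphabet, so that the
fitted model reads as a balance between the cumulated abundances of two
small groups of features:

* **Bin** — coefficients in {0, 1}: "is the cumulated relative abundance of
  this group of species above the threshold?"
* **Ter** — coefficients in {−1, 0, 1}: "does the cumulated abundance of
  group A exceed that of group B by more than the threshold?"
* **Ratio** — a numerator group and a denominator group with ratio factor
  θ: "is the cumulated abundance of group A more than θ times that of
  group B?" The score sum(A)/sum(B) does not depend on the sample's total,
  so ratio decisions are invariant to per-sample rescaling — the natural
  choice for compositional data.
* **TerLog** — a Ter model fitted on log-transformed abundances, i.e. a
  multiplicative balance. `btrsign` treats it as Ter on
  `log_transform(m)`; the two routes are identical end-to-end.

Model size k is the number of selected features. The decision compares the
score against a threshold with a learned direction; a sample strictly
beyond the cut is assigned the positive class, ties go to the non-positive
class. The positive class defaults to the lexicographically larger label —
a labeling convention only, since the direction is learned.

## Threshold fitting

For a fixed structure, the threshold is the cut minimizing training
misclassifications, found by sorting the scores and sweeping the cumulative
error over every admissible cut (midpoints between distinct scores plus
sentinels beyond the extremes), for both directions. This equals exhaustive
enumeration over cuts × directions by construction and is verified against
an independent brute-force oracle in the tests. Ties resolve to the widest
margin, then the smaller cut, then `score_greater`, so refits are
bit-reproducible. The sweep is implemented in C++ (it runs ~10^5 times per
search); an R transcription of the same algorithm is kept beside it as the
readable reference.

Two sentinel rules keep ratio scores defined on sparse data: `x/0 → Inf`
for `x > 0`, and `0/0 → 0`. A degenerate fit that sends every sample to
the positive side is represented by a below-minimum sentinel cut, which for
ratio models can be ≤ 0 even though a fitted ratio factor is normally
positive; we accept this representation rather than make the all-positive
rule unrepresentable.

## Search

Exact learning over discrete coefficients is combinatorial, so the package
searches with a genetic algorithm: one island per model size k (so the
later size-penalized comparison across k is fair), populations of 200,
100 generations, tournament selection of size 2, elitism on the top 10%,
crossover rate 0.8 and per-feature mutation rate 0.2. These are
conventional GA settings; all are `search_config()` fields. Initial
populations mix models seeded from the top Mann-Whitney-ranked features
(signs from class-wise enrichment; the first model of each island is
exactly the top-k set) with uniform random structures. Populations store
canonical forms — features sorted, first coefficient positive — because a
ternary rule and its global sign flip, or a ratio and its side swap, are
the same decision family once threshold and direction are refitted.

`exhaustive_search()` enumerates every canonical structure up to `k_max`
(with a guard bound on the model count) and serves as the ground-truth
oracle: on small planted problems (p = 12, n = 60, k ≤ 3) the GA reaches
the exhaustive optimum in ≥ 95% of seeded runs, which the test suite
re-verifies. An optional `patience` parameter stops an island after that
many generations without improvement; the default (`Inf`) always spends
the full budget. The recovery and importance studies in the tests use
patience 10–15, which on strongly planted signals converges well before
the budget.

## Selection and the family of best models

The final model maximizes `accuracy − λk` with λ = 0.01: one extra feature
must buy strictly more than 1% training accuracy. Penalized values are
rounded to 10 decimals before the argmax so that a gain of exactly λ is a
tie, resolved toward the smaller model (then by feature names —
deterministic under reordering).

The family of best models (FBM) collects every searched model whose
accuracy lies within a statistically equivalent window of the best,
treating the number of correct classifications as binomial: with best
accuracy a over n training samples, `window = qnorm(1 − p) ·
sqrt(a(1−a)/n)` at p = 0.05 (one-sided normal approximation; an exact
binomial quantile is available via `exact = TRUE` and differs negligibly
for n ≥ 30). Note the window *widens* as p shrinks — a stricter
equivalence level declares more models indistinguishable from the best.
Members are deduplicated by structure, ignoring the threshold. The window
is computed from training accuracy within each CV fold; computing it from
CV accuracy would be the main alternative, and would require nesting.

## Evaluation harness

`cross_validate()` runs repeated stratified k-fold CV (10×10 for
classification, 20×5 for regression by convention). Stratification keeps
class proportions within ±1 sample per fold; the folds depend only on the
labels, scheme and seed, so different learners see identical splits and
`compare_learners()` can apply a paired t-test over the per-split
differences (verdicts: better/worse/equivalent at P ≥ 0.05; all-zero
differences are equivalent by definition, a constant nonzero difference is
significant with its sign). Every data-dependent step — SD filtering,
Mann-Whitney ranking, threshold fitting — happens inside the learner's
`fit` on training folds only. Comparators (elastic net with mixing 0.5,
random forest with 500 trees, linear SVM) are adapter-wrapped third-party
implementations; RF and SVM receive the top-k Mann-Whitney features, the
elastic net takes the first k features entering its own regularization
path. A training fold in which no feature varies at all falls back to
majority-class prediction, because the underlying libraries reject (or, for
tree ensembles, stall on) zero-variance predictors.

On pure-noise data, cross-validated accuracy of a model *selector* sits
slightly below the majority-class rate — selection fits fold noise whose
complement is the test fold. This pessimism is the honest null behavior;
information leakage would push accuracy above the baseline instead. The
test suite therefore checks the two-sided chance-level band on
constant-feature data (where every learner collapses exactly to the
majority rule) and a one-sided no-inflation bound on noise data.

## Feature importance

Importance is permutation-based mean decrease accuracy over the FBM:
within each CV fold, for each feature used by that fold's FBM, the
feature's values are permuted across the fold's held-out samples, each FBM
model's held-out error is recomputed, and the error increase is averaged
over all FBM models (models not using the feature contribute exactly zero)
and over `n_permutations` draws (default 10 — a cost/variance compromise).
The final MDA averages the folds and carries the SEM across folds. The
held-out set here is the CV test fold; a bootstrap out-of-bag scheme would
be the alternative reading. Permutation is one feature at a time, and the
error is always 1 − accuracy regardless of the search metric.

## FBM distillation

`model_feature_table()` turns an FBM into a signed models × features
incidence matrix. `cooccurrence_network()` scores each feature pair by the
phi coefficient of co-presence across FBM models — positive edges mark
features that predict together (complementarity), negative edges features
that replace one another (redundancy) — and keeps the top 5% strongest
edges by default. This is a deliberate simplification: a consensus
network-reconstruction pipeline over the incidence table would be a
separate undertaking, so the network here is qualitative (co-presence vs
replacement), not a numerical reproduction, and it is undirected.
`data_vs_model_correlation()` pairs each edge's abundance correlation in
the data with its model co-presence: interchangeable features show up
correlated in the data and mutually exclusive in the models.

## Synthetic data

`generate_abundance()` draws per-feature log-normal abundances (per-feature
log-means drawn once from N(0, 1.5), log-SD 1), zeroes entries below a
detection quantile (default sparsity 0.3, each sample's largest entry
always kept), and closes each sample to sum 1. Log-normal + closure gives
the heavy-tailed, zero-inflated profiles of shotgun relative abundances
while keeping per-feature dispersion directly controllable, which a
Dirichlet draw would not. `plant_labels()` applies a planted BTR model
(threshold defaulting to the median score, giving balanced classes) and
flips each label with probability `label_noise` (default 0.05). What the
generator does **not** emulate: taxonomic correlation structure, batch
effects, varying sequencing depth, real prevalence patterns. Passing tests
show the machinery is correct and recovers planted structure under
realistic noise; they do not certify performance on real cohorts.

The test suite exercises: threshold optimization on 1,000 random
instances against brute force; GA-vs-exhaustive agreement on 50 planted
datasets (p = 12, n = 60, k ≤ 3); ratio scale-invariance on 100 random
models; recovery of a planted 3-feature signal (p = 100, n = 300, 5% label
noise, 20 runs) and its top MDA rank; chance-level CV on null data for all
learners; and calibration of the paired comparison at the nominal 5%
level. Problem sizes were chosen so the full suite documents the method's
behavior at desk scale.

## Numerical notes

* Ratio decisions are exactly invariant to per-sample rescaling;
  the *scores* are bit-identical under power-of-two rescaling (exact in
  IEEE-754) and agree to a few ulp under arbitrary positive rescaling,
  because the inputs themselves are rounded before the ratio is formed.
* Model JSON is written with 17 significant digits, so reloaded models
  reproduce predictions bit-identically.
* The SD-elbow filter removes features with SD at or below the sorted-SD
  curve's point of maximum central second difference; ties take the
  smallest SD, a flat curve filters nothing, SD = 0 features are always
  removed. The sorted curve (not a density estimate) is our reading of
  "the distribution of the feature's standard deviation".
* Relative-abundance sub-tables (after feature filtering) keep their scale
  tag: scores remain fractions of the *original* sample total, which is
  how fitted cuts are meant to be read ("x% of total microbial
  abundance").

## Limitations

Binary classification and scalar regression only (no multiclass); no
taxonomic aggregation, rarefaction or BIOM parsing; the co-occurrence
network is undirected and association-based; comparator learners are used
with fixed, conventional hyperparameters rather than tuned per dataset.
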