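---
title: "A two-stage bagged model for skin sensitization hazard and potency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A two-stage bagged model for skin sensitization hazard and potency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinsens)
library(dplyr)
```

## The problem

Regulatory identification of human skin sensitizers increasingly relies on
*defined approaches*: fixed combinations of non-animal information sources.
`skinsens` implements one such approach as a reusable pipeline. Substances are
described by three kinds of features:

* **In vitro assay readouts** covering the adverse-outcome pathway: DPRA
  cysteine- and lysine-peptide depletion (percent, continuous), the
  KeratinoSens EC1.5 (the interpolated concentration giving 1.5-fold
  luciferase induction; continuous, lower = more potent), the binary h-CLAT
  call, and the SENS-IS class (ordinal from *extreme* to *negative*,
  binarized so that any sensitizer class counts as positive).
* **Physicochemical descriptors**, treated as opaque named numeric columns.
  The package never computes descriptors; it prunes and scales whatever
  columns the substance table carries.
* **One scalar distilled from a SMILES language model**: the grand mean of
  the last-hidden-layer token embeddings
  (`roberta_embedding_mean`). Mean-over-tokens-then-dimensions equals the
  grand mean, so the pooling order is immaterial.

Human reference labels are six potency categories: 1-4 are sensitizers
(1-2 strong, "1A"; 3-4 weak, "1B"), 5-6 non-sensitizers ("NC").

## The model

Classification is a cascade of two binary stages (`fit_cascade()`):

1. **Hazard**: sensitizer vs non-sensitizer, trained on all substances.
2. **Potency**: 1A vs 1B, trained on the *true* sensitizers only. Training
   on true rather than stage-1-predicted sensitizers keeps the potency model
   evaluable on every labeled sensitizer, independent of stage-1 errors;
   both evaluation protocols (cascaded and independent) are exposed in
   `predict()`.

Each stage is a **bagged ensemble of five gradient-boosted tree
classifiers**. Five bootstrap subsets are drawn with replacement, each
containing 80% of the training substances (rounded half away from zero; 78
of 97). Each subset's learner is tuned by exhaustive grid search over
learning rate \{0.01, 0.1, 0.2\}, boosting rounds \{50, 100, 200, 300,
500\}, depth \{3, 5, 7, 9\}, row subsampling \{0.6, 0.8, 1.0\} and the
positive-class weight (\{0.5, 1\} for the hazard stage, \{1, 2\} for the
potency stage), scored by stratified 5-fold cross-validated **balanced
accuracy** — the mean of sensitivity and specificity, robust to the class
imbalance these data always carry. Ties prefer the first grid point in
lexicographic enumeration order, which makes tuning deterministic.
Prediction is by **majority vote** of the five hard (0.5-threshold) calls;
with five voters the vote fraction lies in \{0, 0.2, ..., 1\} and a tie is
impossible.

### Preprocessing

* EC1.5 is right-censored at 2000: larger values are unreliable to measure
  and are substituted with the cap. A prediction-time EC1.5 exactly at the
  cap is flagged by `domain_flags()` because censored values inflate the
  false-negative risk.
* Rows missing any required feature are removed (`drop_incomplete()`); the
  approach does not impute assay results.
* Descriptors are pruned by Pearson correlation: a greedy scan in column
  order keeps the first member of each correlated group and drops any later
  feature whose |r| with a kept feature reaches 0.75. Absolute correlation
  is used because a negatively duplicated descriptor is just as redundant;
  the greedy-first rule is deterministic and order-stable. Pruning applies
  to descriptors only — assay features and the embedding scalar are never
  pruned.
* Retained descriptors and the embedding scalar are standardized to mean 0
  and *population* variance 1 (denominator n, so the training variance is
  exactly 1); assay readouts stay on their native scales, which tree
  ensembles do not require rescaled. Scalers are fitted on training rows
  only and reapplied to test rows.
* The train/test split is stratified by potency category with a total test
  size of ceiling(0.2 n) and largest-remainder allocation across
  categories, reproducing a 97/25 partition at n = 122. Singleton strata
  go to training with a warning.

### Feature selection

`average_importance()` averages each feature's gain (loss-reduction)
importance over the five learners; features a learner never splits on
contribute zero. `top_k_features()` returns the k best *including every
feature tied with the k-th* (a tie at ranks 15-16 yields 16 features).
`substitute_assay()` implements the practical refinement of swapping the
least important in vitro assay for the best not-yet-selected feature —
worth doing when it costs no accuracy, because it removes an entire assay
from the testing burden. `compare_feature_sets()` refits the full bagged
pipeline per candidate list on identical splits and seeds and selects by
held-out balanced accuracy, breaking ties toward fewer features and then
toward the substituted variant. Selecting on the held-out set mirrors the
protocol of the study this package emulates; the associated optimism risk
is inherent to that protocol and worth remembering when quoting the
selected model's test performance.

### Evaluation

`metrics_from_confusion()` evaluates accuracy, sensitivity, specificity,
balanced accuracy and F1 exactly from confusion counts, reporting a metric
with a zero denominator as `NA` rather than 0. Because a majority vote
yields both a hard label and a graded score, "AUC-ROC" is ambiguous;
`auc_variants()` therefore reports both: `auc_hard`, the two-point ROC
area of the hard labels, which equals balanced accuracy identically, and
`auc_score`, the Mann-Whitney area over vote fractions with ties counted
one half. The 3-class report (`potency_table()`) gives overall accuracy
and, per human class, the fractions correctly classified, underpredicted
and overpredicted on the NC < 1B < 1A ordering; the three always sum to 1.

### Explanation

`shap_attributions()` computes exact path-dependent TreeSHAP attributions
on the margin (log-odds) scale — where additivity is exact for tree
models — in double precision, then averages them without weights across
the five learners. The implementation routes substances through the trees
at single precision (the storage precision of splits and features) so its
margins agree with the library's, and is cross-checked in the test suite
against both the tree library's own attributions and a brute-force
two-player Shapley enumeration. Because the final call is a majority vote
while the averaged attributions reconstruct the *mean* margin, a minority
of learners with extreme margins can make the sign of the attribution sum
disagree with the vote; `vote_shap_concordance()` flags such substances as
expected behavior, not errors.

## The synthetic data generator

The original substance table is not redistributable, so
`simulate_substances()` generates datasets with the same statistical
shape for development and testing. A latent potency score
`u = (7 - category)/6 + N(0, noise_sd)` drives every readout
monotonically, with a global effect multiplier `effect` (β):

* EC1.5 `= min(2000, exp(8 - 4βu + ε))` — falls with potency, right-censored
  at the cap, with censoring concentrated in the low-potency categories;
* C- and K-peptide depletion `= 100·logistic(-3 + 6βu + ε)`;
* h-CLAT `~ Bernoulli(logistic(-1 + 3βu))`;
* SENS-IS from thresholding `ū + β(u - ū) + ε` into the five classes,
  where `ū` is the expected potency score — centering on `ū` makes the
  class carry label signal only through β (at β = 0 it is pure noise,
  at β = 1 it reduces to `u + ε`);
* descriptors in correlated blocks (shared-factor construction, default 3
  blocks of 10 at within-block r = 0.85), with only the first block shifted
  by βu;
* the embedding scalar `= 0.5βu + N(0, 1)` — a deliberately weak signal;
* SMILES drawn from a bundled list of 150 valid strings, so the embedding
  pipeline has real text to chew on without any chemistry dependency.

Default conditions: n = 122 substances with category probabilities
(0.10, 0.10, 0.24, 0.24, 0.16, 0.16) — the collapsed 1A:1B:NC mix of
0.2:0.48:0.32 matching the emulated study's test composition — β = 2,
`noise_sd = 0.05` and `assay_noise_sd = 0.5`. The latent noise is chosen
small relative to the 1/6 gap between adjacent categories so that the
default β = 2 regime is a genuine strong-signal recovery setting
(adjacent-category confusion at the hazard boundary ≈ 5%, Bayes balanced
accuracy ≈ 0.98); at β = 0 every feature-label association vanishes and
held-out performance sits at chance. These two regimes anchor the
end-to-end correctness tests: the pipeline must recover planted signal
(balanced accuracy ≥ 0.85 at β = 2, n = 400) and must not invent signal
(within [0.35, 0.65] at β = 0 across seeds).

What the generator does **not** emulate: real descriptor marginals or
inter-assay error correlations, chemical realism of the SMILES-to-label
relationship (the bundled strings are decorrelated from the labels), or
borderline substances whose assays genuinely disagree. Passing the
recovery tests therefore demonstrates that the pipeline's machinery is
sound, not that any particular accuracy will be attained on real
substances.

## Numerical and design choices

* **Determinism**: every stochastic step (splits, bootstrap draws, fold
  assignment, tree fitting) is keyed to the run seed; fits are
  single-threaded; training rows are canonically sorted by substance id
  before sampling, so results are invariant to row order. Identical
  config and seed give byte-identical manifests.
* **Embedding backend**: the pretrained-transformer provider is pluggable
  and records its checkpoint identity with every feature cache, because
  embeddings are checkpoint-dependent. The default offline backend is a
  deterministic character-trigram hash producing 768-dimensional
  pseudo-embeddings — a stand-in with the right geometry for exercising
  the pooling and caching machinery, not a chemical model. Embeddings are
  extracted in evaluation mode; dropout is a training-time regularizer of
  the backbone and plays no role at inference.
* **Grid size as a compute choice**: the full 360-point grid is the
  package default; the test suite and the acceptance script pass reduced
  grids (1-8 points) and moderate problem sizes (n = 122-500, 5-20 seeds)
  so the whole suite runs in about a minute on one CPU. Grid size affects
  how well each base learner is tuned, not what the pipeline computes.
* **Degenerate inputs**: zero-variance features are rejected by the
  standardizer (by name) and dropped by the pruner with an
  undefined-correlation note; single-class bootstrap subsets abort with a
  clear message; a minority class smaller than the fold count shrinks the
  fold count with a warning; category labels outside 1..6 are domain
  errors.
* **Reported precision**: percentages are rounded half-up to one decimal
  only in printed reports; internal values stay exact fractions.

## Limitations

The approach inherits the limits of its inputs: substances outside the
training feature ranges (see `fit_domain_ranges()`), or with EC1.5 at the
censoring cap, are predicted less reliably — the false-negative risk of
censored EC1.5 is the single most consequential failure mode, since EC1.5
is typically the dominant feature. The scalar embedding discards all
token-level structure, so no statement about *which* substructure drives a
prediction is possible from it. And with training sets of about a hundred
substances, test-set-based model selection has real variance; the reported
metrics should be read with that in mind.
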