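---
title: "Accuracy-weighted multimodal feature fusion: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accuracy-weighted multimodal feature fusion: models, choices, and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(elmfusion)
```

## The problem

Case--control neuroimaging studies routinely extract many *measures* per
subject — cortical thickness per parcel, surface area, subcortical volumes,
per-region global functional connectivity, ICA-derived connectivity vectors —
each a homogeneous block of features. Concatenating all blocks into one
matrix ("simple concatenation") treats a weakly informative measure the same
as a strongly informative one. The fusion scheme implemented here instead
weights each block by how well it classifies on its own, then concatenates.

## The weighting rule

Let $A_1, \dots, A_m$ be cross-validated accuracies of the $m$ measures and
$A_{\max}$ their maximum. Each measure's residual is $R_i = A_{\max} - A_i$
and its weight

$$W_i = 1 - R_i = 1 - A_{\max} + A_i \in [0, 1].$$

The best measure always receives weight exactly 1; every other measure is
down-weighted by precisely its accuracy deficit. Weights depend only on
differences $A_i - A_{\max}$, so they are invariant to shifting all
accuracies by a constant — `compute_weights()` asserts both properties.
Weights are kept at full precision internally; published tables round to 4
decimals, which is how `scripts/acceptance.R` reports them.

Three concatenations are provided, all column-count preserving:

* **Simple**: plain block concatenation (`simple_concat()`).
* **Simple weighted**: $[W_1 M_1 \,\|\, \cdots \,\|\, W_m M_m]$
  (`simple_weighted_concat()`); no normalizing division, as the scheme's
  published formula has none.
* **Hybrid weighted**: cortical measures are weighted and divided by the sum
  of cortical weights; subcortical *and whole-brain* measures form a second
  block divided by the sum of its distinct weights; ICA connectivity
  features are appended unweighted (`hybrid_weighted_concat()`).

Two design choices here were genuinely open:

1. **Scaling order.** Each measure is min--max scaled to $[-1, 1]$ *before*
   weighting, and the fused matrix is not rescaled per feature afterwards.
   Rescaling after weighting would restore every column to the same range
   and cancel the weights exactly; this ordering is the only one under
   which the weights can influence the classifier. The fusion functions
   therefore operate on pre-scaled blocks (`scale_dataset()`, or per-fold
   scalers inside `fused_nested_cv()`), and the fused matrix is passed to
   the classifier as-is.
2. **Whole-brain blocks.** The reference feature table lists whole-brain
   intensity and whole-brain global connectivity under the same measure
   labels as their subcortical counterparts, and its weight table has
   exactly 12 entries for 14 feature blocks. The only reading consistent
   with both is that whole-brain blocks share the like-named subcortical
   weights; `feature_measure()` carries this as a `weight_key`, accuracies
   are estimated per key (blocks sharing a key are concatenated), and a
   shared weight is counted once in the hybrid block's normalizing sum.
   This preserves the design's 748-column total with 449 cortical,
   76 + 52 = 128 subcortical + whole-brain, and 171 ICA columns.

## The classifier

The extreme learning machine (`elm_train()`) is a single-hidden-layer
network whose hidden layer is never trained: input weights and biases are
drawn uniformly on $[-1, 1]$ (the classical choice; the source formulation
leaves the distribution open) and only the output weights are learned, as
the minimum-norm least-squares solution $\beta = H^+ T$ with $H$ the hidden
activations and $T$ the $\{-1, +1\}$ one-hot targets. Numerical choices:

* activation: logistic sigmoid by default (`tanh` by flag) — unstated in
  the source formulation, so the classical ELM default is used;
* pseudo-inverse by SVD with relative singular-value cutoff $10^{-12}$, no
  ridge term (the original, unregularized formulation);
* prediction by argmax of the output scores, exact ties broken toward the
  first class of the encoding (so an all-zero model predicts the first
  class deterministically);
* features are expected in $[-1, 1]$; `minmax_scale_fit()` maps the
  training range there, sends constant training features to 0, and lets
  test values extrapolate beyond $\pm 1$ rather than clipping.

The single hyperparameter is the hidden-node count $N$.
`tune_hidden_nodes()` scans a candidate range (the reference protocol uses
$90{:}220$) and takes the first maximizer of inner-CV accuracy. The
reference protocol's description of tuning "for maximum test accuracy"
implies selection on outer test folds; the honest default here tunes by
stratified CV inside the training partition only, with
`tuning_mode = "paper_replication"` available to reproduce the
tune-on-test protocol. Candidates at or above the inner training size warn
(interpolation regime) but still run.

## Evaluation and significance

`nested_cv()` implements stratified repeated $k$-fold CV ("10-by-10" by
default): per repeat a fresh stratified partition, per fold scaler fitting,
tuning, training, and held-out prediction, with per-fold confusion counts
retained. Stratification places each class's remainder subjects on the
least-loaded folds, so with 72 + 72 subjects and 10 folds every fold has 14
or 15 subjects and 7--8 per class. Undefined metric ratios (0/0, e.g. PPV
with no positive predictions) are reported `NA` and excluded from
aggregation rather than coerced; the headline accuracy is pooled over all
fold counts, which makes it exactly recomputable from the stored confusion
counts. All randomness derives from the config seed via documented child
seeds (`cv_repeat_seed()`, `cv_fold_seed()`), so an external loop can
replay any fold — the test suite does exactly this.

`permutation_test()` reruns the identical CV procedure (scaling, tuning,
training) on randomly permuted labels and reports the add-one estimator
$p = (1 + b)/(1 + m)$, $b$ the number of permuted statistics at least as
large as the observed one. The estimator can never return 0, attains the
floor $10^{-4}$ at $m = 10{,}000$ (the reference protocol's count) when no
permutation reaches the observed statistic, and counts ties against
significance. Whether published permutation protocols rerun tuning per
permutation is typically unstated; the stricter full rerun is what this
implementation does.

For fused classification, `fused_nested_cv()` offers two weighting
protocols. `"whole_dataset"` computes accuracies, weights, and scalers once
from all subjects — the protocol under which published weight tables are
produced, but one in which test subjects inform the weights.
`"within_fold"` (the leakage-free default) re-estimates accuracies and
weights inside every outer training partition via a secondary CV; it is
slower and its weights vary by fold, which is the honest price of the
nested protocol. Both are first-class because replicating the published
procedure and evaluating it honestly are different tasks.

## Connectivity features

The post-preprocessing connectivity math works on plain delimited matrices:

* `unit_normalize()` demeans each voxel's series and scales it to unit
  Euclidean norm, after which Pearson correlations are dot products.
* `voxelwise_global_connectivity()` computes each voxel's mean correlation
  with the whole volume as $u_i \cdot \bar u$ — never forming the
  $M \times M$ correlation matrix. The mean *includes* the voxel's own
  $r = 1$ term: that is what the algebra of the unit-norm trick yields, and
  it makes the GCOR scalar exactly the map mean. Users wanting the
  self-exclusive mean can convert via $(Mv - 1)/(M - 1)$.
* `gcor()` returns the *squared* norm of the voxel-averaged unit-norm
  series, which equals the mean of all $M^2$ pairwise correlations and lies
  in $[0, 1]$. Descriptions of this quantity sometimes say "the
  $\ell_2$-norm of the averaged series", which taken literally is the
  square root of the mean correlation; since only the squared version *is*
  the mean correlation, the squared form is the default and
  `squared = FALSE` provides the literal reading.
* `fisher_z()` applies $z = \operatorname{atanh}(r)$ with $|r|$ clipped at
  $1 - 10^{-7}$ so maps stay finite. ROI averaging (`roi_average()`)
  defaults to operating on $z$-scale maps, since the transform is described
  upstream of ROI extraction; pass an $r$-scale map to average on the
  correlation scale instead.
* `component_connectivity()` correlates $K$ ICA component time-courses and
  vectorizes the strict upper triangle in row-major order —
  $K(K-1)/2$ features, 171 for the 19 retained components of the reference
  design.

Pearson correlations are computed via the unit-norm route (population
normalization); the normalization constant cancels in every correlation.

## The synthetic generator

`generate_dataset()` draws class-conditional Gaussian feature blocks: an
`frac_informative` fraction of each measure's columns (the first ones, at
least one) has class means separated by `effect_size` noise-SD units
(placed symmetrically about zero, patients higher) and shares an
equicorrelation `rho` through a per-subject latent factor; remaining
columns are independent noise. Effect sizes in noise-SD units make
per-feature separability analytic: AUC $= \Phi(\delta/\sqrt{2})$.

`table2_spec()` fixes the reference geometry — 72 + 72 subjects, the 14
feature blocks (449 cortical, 76 subcortical, 52 whole-brain, 171 ICA; 748
total) under 12 weight keys. The per-measure effect sizes are fixed
plausible defaults chosen once: 0.5--0.9 across structural measures
(surface area lowest at 0.5, curvature highest at 0.9), 0.6--0.8 for
subcortical and whole-brain blocks, and 1.0 for the ICA connectivity block
so that it is the most discriminative measure, as in the reference study's
ranking; `frac_informative = 0.3` and `rho = 0.2` reflect that only a
minority of regions carry group differences and that features within a
measure are correlated. No attempt is made to mimic real morphometric
distributions (skewness, site effects, age/sex structure, measure-to-measure
dependence beyond the shared labels): the generator tests the method's
statistical machinery, not the biology, so passing tests demonstrate
correct mechanics and sane statistical behavior — not expected accuracy on
real cohorts.

## Problem sizes used by the test suite

Tests run the machinery at deliberately small scale, chosen as the smallest
sizes at which each property is meaningful: oracle equivalences on 50-voxel
volumes and 20-to-24-subject training sets; CV bookkeeping on 10--144
subjects; the permutation-null calibration on 40 subjects with 20 null
features, 200 permutations and 200 replicates (rejection rate at
$\alpha = 0.05$ checked against a loose [0.01, 0.12] band); fusion behavior
checks at the design's 72-per-group cohort with small feature blocks. The
full 90:220 node search and 10,000-permutation protocol are available but
not exercised wholesale in tests.

## Known limitations

* The permutation test is implemented for a fixed feature matrix; in
  `run_experiment()` the within-fold weighting protocol therefore reports
  no permutation p-value (the whole-dataset protocol does). Permuting
  through the full within-fold weight re-estimation is a straightforward
  but expensive extension.
* Only binary classification is exercised; the ELM interface would extend
  to more classes but is untested there.
* The generator's Gaussian blocks cannot reveal failure modes specific to
  heavy-tailed or strongly dependent real features.
* With small cohorts the ELM's accuracy is sensitive to the hidden-node
  count (it interpolates and overfits once $N$ approaches the training
  size); the node search exists precisely because of this.
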