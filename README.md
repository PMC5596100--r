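# elmfusion

Accuracy-weighted fusion of multimodal feature tables with an extreme
learning machine classifier, for two-group (case–control) designs built
from neuroimaging-derived measures.

## The problem

Structural and functional MRI pipelines reduce each subject to a set of
*measures* — cortical thickness per parcel, surface area, subcortical
volumes and intensities, per-region global functional connectivity, the
vectorized correlation matrix of ICA component time-courses. Concatenating
all of these blocks into one classifier input treats every measure as
equally informative. This package implements a fusion scheme that first
scores each measure by its own cross-validated accuracy and then weights
its block accordingly before concatenation.

## The method

With per-measure nested-CV accuracies `A_1 … A_m` and `A_max = max_i A_i`,
each measure's weight is

    W_i = 1 − A_max + A_i            (W_i ∈ [0, 1], best measure gets 1)

Three concatenations are provided, all preserving the total column count:

* **simple** — `[M_1 ‖ … ‖ M_m]`
* **simple weighted** — `[W_1·M_1 ‖ … ‖ W_m·M_m]`
* **hybrid weighted** — cortical blocks weighted and divided by the sum of
  cortical weights, subcortical + whole-brain blocks likewise by their
  summed weights, ICA connectivity features appended unweighted

Each measure is min–max scaled to `[−1, 1]` *before* weighting; the fused
matrix is never rescaled per feature afterwards (doing so would cancel the
weights exactly).

Classification uses an extreme learning machine: a single hidden layer
with random fixed weights (uniform on `[−1, 1]`), output weights solved in
closed form as `β = pinv(H)·T`, and a hidden-node search (`90:220` in the
reference protocol) as the only hyperparameter. Evaluation is stratified
repeated ("10-by-10") nested cross-validation with confusion-matrix
metrics and a permutation test using the add-one estimator
`p = (1 + b)/(1 + m)`.

The package also covers the post-preprocessing connectivity feature math —
per-voxel global-connectivity maps via the unit-norm trick, Fisher z,
atlas-ROI averaging, the GCOR scalar, ICA component-connectivity
vectorization — and a seeded synthetic-data generator reproducing the
reference feature-table geometry (72 + 72 subjects, 748 features across 14
blocks under 12 fusion weights).

## Worked example

The published worked example of the weighting rule — the 12 per-measure
ELM test accuracies of the reference schizophrenia-vs-control study —
ships with the package:

```r
library(elmfusion)
compute_weights(reference_measure_accuracies())
#> <weight_vector>
#>  rank        measure accuracy weight
#>     1      Group ICA   0.9295 1.0000
#>     2      Curvature   0.9238 0.9943
#>     3        SC GCOR   0.9124 0.9829
#>     4      Thickness   0.9114 0.9819
#>     5 Overall Volume   0.9105 0.9810
#>     6         Volume   0.9063 0.9768
#>     7  Cortical GCOR   0.9057 0.9762
#>     8  Thickness STD   0.9048 0.9753
#>     9   SC Intensity   0.8990 0.9695
#>    10      SC Volume   0.8989 0.9694
#>    11             WM   0.8956 0.9661
#>    12   Surface Area   0.8813 0.9518
```

The group-ICA measure, having the highest standalone accuracy, anchors the
scale at weight 1; every other measure is down-weighted by exactly its
accuracy deficit.

An end-to-end run on synthetic data (five measures of programmed quality,
36 subjects per group, 5-fold CV repeated twice):

```r
measures <- data.frame(
  label = c("cortA", "cortB", "scA", "scB", "ica"),
  group = c("cortical", "cortical", "subcortical", "subcortical", "gica"),
  n_features = c(8, 8, 6, 6, 10),
  effect_size = c(1.5, 0.5, 0.8, 0.2, 2),
  frac_informative = 0.5, rho = 0.2)
cfg <- run_config(spec = synth_spec(measures, n_per_group = c(36, 36)),
                  classifier = elm_spec(n_hidden = 40),
                  cv = cv_config(n_folds = 5, n_repeats = 2, seed = 7),
                  weight_mode = "whole_dataset", seed = 7)
run_experiment(cfg)
#> <experiment_report> seed 7, weight mode 'whole_dataset'
#>
#> Per-measure nested-CV accuracy and fusion weight:
#>  rank measure accuracy weight
#>     1     ica   0.8472 1.0000
#>     2   cortA   0.7222 0.8750
#>     3     scA   0.6389 0.7917
#>     4   cortB   0.5556 0.7083
#>     5     scB   0.5417 0.6944
#>
#> Fused models:
#>    method train_accuracy test_accuracy sensitivity specificity     f1    ppv
#>    simple              1        0.8056      0.8321      0.7750 0.8090 0.8019
#>  weighted              1        0.8472      0.8607      0.8339 0.8477 0.8547
#>    hybrid              1        0.8681      0.8589      0.8732 0.8617 0.8914
#>     npv p_value
#>  0.8352      NA
#>  0.8722      NA
#>  0.8835      NA
```

Measures with larger programmed effect sizes earn larger weights, and the
weighted fusions beat plain concatenation on the same data and seeds. The
`weight_mode = "within_fold"` option re-estimates the weights inside every
training fold instead, keeping held-out subjects out of the weighting (see
the methods vignette, `vignettes/weighted-fusion.Rmd`).

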