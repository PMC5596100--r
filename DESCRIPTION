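Package: elmfusion
Title: Weighted Multimodal Feature Fusion and Extreme Learning Machine
    Classification for Neuroimaging-Derived Feature Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Accuracy-driven weighted concatenation of multimodal feature
    tables (structural and functional brain measures) for two-group
    classification. Implements simple, simple-weighted, and hybrid-weighted
    feature concatenation with per-measure fusion weights derived from
    cross-validated accuracies, an extreme learning machine classifier with
    hidden-node search, stratified repeated nested cross-validation with
    permutation-based significance testing, post-preprocessing global
    functional connectivity features (voxelwise connectivity maps, Fisher z,
    ROI averaging, the GCOR scalar, ICA component connectivity
    vectorization), and a seeded synthetic-data generator reproducing the
    feature-table geometry of a balanced two-group study design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
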