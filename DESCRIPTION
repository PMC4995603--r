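Package: lesiondecode
Title: Decoding Upper-Limb Motor Impairment from Structural Lesion Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for predicting a composite upper-limb motor-impairment
    score from stroke lesion-probability maps. Covers lesion segmentation
    (probability threshold plus minimum cluster size), hemispheric flipping to
    a canonical side, eight region-of-interest strategies (atlas, motor
    subset, corticospinal tract, functional mask, lesion-symptom-mapping
    ROIs, lesion union, whole brain), voxel-pattern and lesion-load feature
    extraction, Gaussian process regression on a linear covariance, multiple
    kernel learning over per-region kernels by marginal-likelihood ascent,
    and leakage-controlled k-fold cross-validation. Includes a synthetic
    cohort generator (ellipsoidal soft-edged lesions, mirrored atlas, four
    correlated clinical scales with floor/ceiling clipping) so the full
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
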