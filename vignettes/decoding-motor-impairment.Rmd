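---
title: "Decoding motor impairment from structural lesion maps: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor impairment from structural lesion maps: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

After a stroke, the location and extent of the lesion carry information
about a patient's upper-limb motor impairment. `lesiondecode` implements a
complete decoding pipeline that predicts a composite motor score from
structural lesion information: per-voxel lesion probabilities are turned
into features under several region-of-interest (ROI) strategies, a
Gaussian process (GP) regressor with a linear covariance maps features to
the score, and everything is evaluated by a strictly leakage-controlled
10-fold cross-validation. A multiple-kernel variant learns a relevance
weight per anatomical structure.

Patient imaging cannot ship with a package, so the package includes a
first-class synthetic cohort generator that emulates the statistical
structure the pipeline assumes. Every stage is exercised and tested
end-to-end on generated data.

## The composite target

Motor impairment is assessed on four correlated scales: the Action
Research Arm Test (ARAT), grip strength (GS), the Motricity Index (MI) and
the Nine-Hole Peg Test (NHPT, a timed test, so it *increases* with
impairment). A single target is extracted as the first principal component
(FPC) of the four scores: training-column means are subtracted, the
covariance of the centred training scores is eigen-decomposed, and every
subject is projected onto the leading eigenvector. Using one component
both reduces noise and avoids the floor/ceiling artefacts of the
individual instruments.

Two conventions are fixed here because the eigenvector sign is arbitrary:
the loading vector is oriented so its loadings sum to positive (with a
fall-back to a positive first nonzero loading), and near-ties between the
two leading eigenvalues raise a warning rather than an error. Inside
cross-validation the FPC loadings, the training means and the target's
z-scaling are always fitted on training subjects only and applied frozen
to the test subjects.

## Lesion segmentation and canonical orientation

A lesion-probability volume holds, per voxel, the likelihood in [0, 1]
that the tissue is damaged. Binary lesions are obtained by

```{r}
segment_lesion(prob, threshold = 0.3, min_cluster = 100, connectivity = 26)
```

keeping voxels with probability strictly above 0.3 and then only
contiguous clusters of at least 100 voxels. The threshold is strict (a
voxel at exactly 0.3 is excluded) and the cluster rule is inclusive (a
100-voxel cluster survives; 99 does not). "Contiguous" is not unambiguous
in 3-D, so connectivity is an explicit parameter; the default, 26
(faces + edges + corners), is the most permissive standard definition, and
6 and 18 are available because cluster survival can depend on it.

Subjects whose segmented lesion has strictly more voxels in the left
hemisphere than in the right are mirrored about the mid-sagittal plane, so
that all lesions end up on one side. Three choices are pinned down: the
plane lies *between* the two central voxel columns of an even left-right
axis (no ambiguous centre column); the flip decision uses the binary mask,
since "injury" is what segmentation defines, not raw probabilities; and an
exact left/right tie means no flip — the deterministic least-action rule.
The flip is an involution and conserves lesion volume and probability
mass.

## ROI strategies and feature families

Eight mask strategies delimit which voxels or regions enter the model:
all atlas regions, the corticospinal tract (CST) alone, atlas + CST, the
motor-related subset of the atlas, motor + CST, a functional (task-fMRI
style) mask that arrives unilateral and is mirrored into symmetry, ROIs
from lesion-symptom mapping, and the union of training subjects' lesions.
A whole-brain "region" is additionally available for the one-feature
lesion-load model.

Two feature families are extracted:

* **voxel patterns** — one feature per mask voxel, the raw lesion
  probability there, columns ordered by ascending linear voxel index so
  kernels are bit-for-bit reproducible;
* **lesion load** — one feature per region, the fraction of the region's
  voxels inside the binary lesion. Single-mask strategies (whole brain,
  CST, functional, lesion union) give a one-feature model; for lesion
  load the CST is a single region (left + right union), whereas the
  multiple-kernel analysis keeps the two halves as separate sources to
  match the unilateral atlas structures.

The lesion-symptom-mapping ROIs are rebuilt inside every training fold:
each training subject's composite score is rounded to the closest integer
in −2..2 (ties at .5 away from zero, then clamped), and each voxel
lesioned in at least one training subject is assigned the median rounded
score of the subjects lesioned there. Half-integer medians (even counts)
are rounded toward zero — shrinking toward the neutral category is the
symmetric deterministic choice. This yields five ROIs that partition the
training lesion-union volume. Because every lesioned voxel receives a
median, the union of the five ROIs *is* the training lesion union; the
voxel-pattern "VLSM" and "lesion union" strategies therefore use the same
mask and differ only in the lesion-load parameterization.

## Standardization and the linear covariance

Feature matrices are standardized exactly as the decoding method
prescribes: each row (subject) is first normalized by its Euclidean norm,
then each column (feature) is z-scored with mean and standard deviation
computed on training rows only. Two degenerate cases are fixed: all-zero
rows (a lesion entirely outside the mask) pass through row normalization
unchanged, and constant training columns are centred but not scaled
(divisor 1), which keeps them harmless in the kernel instead of producing
NaNs. The target is z-scored with training mean and SD — the scalar
analogue of the same procedure — and all performance numbers live on that
standardized scale.

A consequence worth stating plainly: row normalization maps every
voxel-pattern row to unit norm, which deliberately removes overall lesion
extent from the representation. For a binary lesion fully inside the
mask, total volume is erased entirely; decoding then relies on *where*
the pattern lies and how many voxels share its mass. This is why even a
noise-free synthetic cohort is decoded well but not perfectly (the
package's regression tests pin mean cross-validated R ≈ 0.77 for such a
cohort rather than 1), and why near-constant columns — if a generator let
probability tails shade off indefinitely — could blow up test z-scores.

The covariance between subjects is the plain dot product, C = XXᵀ,
computed once per fold on the standardized features; test-by-train cross
kernels use the identical scaling.

## GP regression and multiple kernel learning

The regression model is y = f(x) + ε with ε ~ N(0, σₙ²) and a GP prior
over f whose covariance is the linear kernel above. Fitting maximizes the
log marginal likelihood

L = −½ log|K_y| − ½ yᵀK_y⁻¹y − (n/2) log 2π,  K_y = s·C + σₙ²·I,

over a signal scale s and the noise variance σₙ², both log-parameterized
(hence positive), by quasi-Newton ascent (L-BFGS-B) with analytic
gradients ∂L/∂θ = ½ tr((ααᵀ − K_y⁻¹) ∂K/∂θ), α = K_y⁻¹y. The optimizer
runs from the supplied start, a data-scaled start and random restarts,
keeps the best, and never returns less than the likelihood at its start.
A failed Cholesky factorization first receives one jitter of
10⁻⁸·mean(diag) and, inside line searches, a large finite penalty so the
search backs off instead of aborting. Predictions are the standard dual
form: mean k*ᵀα, variance from the Schur complement, floored at −10⁻⁸.
For a linear kernel this mean coincides with primal ridge regression
X*(XᵀX + σₙ²I)⁻¹Xᵀy — one of the package's oracle tests.

The multiple-kernel extension replaces the single covariance by
K = Σᵢ wᵢCᵢ over one kernel per anatomical structure, built from
identically standardized features so the learned weights are
interpretable as source relevance. The marginal likelihood as written
needs an invertible K, and the base model already defines observation
noise, so a σₙ²I term is included and σₙ² is optimized jointly by default
(a fixed value can be supplied instead). Weight positivity is enforced by
optimizing log-weights; nothing sparsifies the solution. Both raw and
sum-normalized weights are reported, together with each source's kernel
scale: a structure never lesioned in the cohort has a near-zero kernel,
its weight is unidentifiable, and the table makes that visible instead of
hiding it.

## Cross-validation without leakage

`run_cv()` deals subjects into k = 10 folds of near-equal size by an
unstratified random permutation (seeded, logged). Within each fold, in
order: FPC loadings and target scaling from training subjects only;
data-dependent masks (lesion-symptom ROIs, lesion union) from training
subjects only; feature standardization from training rows; model fit on
the training kernel; prediction of the held-out subjects. Per-fold
Pearson R and RMSE are averaged arithmetically — exactly as the method
defines its headline numbers, despite the high variance of correlations
over 5 test subjects — and a pooled-prediction R over all held-out
subjects is reported separately as a diagnostic (clearly labelled as
such; it is not the headline statistic). A fold whose predictions or
targets are constant has no defined correlation; such folds are excluded
from the R average and counted in the result metadata. Models are
compared by a two-sided Wilcoxon rank-sum test on their per-fold RMSEs —
taken literally as the unpaired test — with the exact null distribution
when the pooled sample is small (≤ 20) and untied, and the tie-corrected
normal approximation otherwise; identical samples short-circuit to p = 1.

The leakage contract is testable and tested: perturbing a held-out
subject's scores changes that subject's prediction target and nothing
else in its fold — predictions, masks, loadings and scaling statistics
are bit-identical.

## The synthetic cohort

The generator produces what the pipeline consumes, at desk scale:

* **Atlas** — a 32×32×32 grid (full-resolution clinical volumes are
  ~176×224×256; all operations are shape-agnostic, and the test suite
  also runs 16³) with `n_region_pairs` ellipsoidal regions placed in the
  left hemisphere and mirrored exactly, 40% flagged motor, plus one
  tube-shaped CST per hemisphere running inferior-superior. Regions are
  pairwise disjoint inside an ellipsoidal brain mask.
* **Lesions** — one ellipsoid per subject with random centre, volume
  drawn from 40–800 voxels (highly variable extent), random anisotropy,
  probabilities falling from ~1 in the core to 0 through a sigmoid of the
  signed distance to the surface over `edge_softness` (default 1) voxels.
  Lesions are confined to their hemisphere with probability 0.95.
  Sub-percent probabilities are set to 0: real probability maps have a
  noise floor, and infinite sigmoid tails would otherwise create
  near-constant features whose z-scores explode.
* **Scores** — a latent damage score gᵢ = −effect_scale·Σᵥ βᵥ·pᵢ(v) with β
  positive and voxelwise-heterogeneous (log-normal, mean 1) inside the
  designated signal regions, so that damage *within* a region matters and
  summarizing a region by its lesion load loses information. Each scale
  is slope·g + intercept plus Gaussian noise of SD `noise_sd·|slope|`
  (so `noise_sd` is expressed on the latent scale and comparable across
  instruments), then clipped to the instrument's floor and ceiling. The
  NHPT slope is negative, so the principal-component sign convention is
  genuinely exercised. Defaults: effect_scale 0.02, noise_sd 0.1,
  β log-SD 0.5.

All randomness flows from one top-level seed through a documented
per-stage derivation; two runs with the same seed are bit-identical.

What the generator does **not** emulate: tissue segmentation and spatial
normalization (volumes are born in a common space), vascular-territory
lesion shapes, registration error, multi-focal lesions, and correlated
rater noise in the clinical scales. Passing tests therefore demonstrate
the pipeline's correctness and its qualitative behaviour (voxel patterns
beating lesion load when within-region pattern carries signal; chance
performance under shuffled labels), not clinical performance on real
cohorts.

## Problem sizes and runtime choices

The packaged analyses and tests use: 100-subject cohorts on 32³ grids for
the qualitative contrast runs, 50 subjects for the worked model grid,
20–30 subjects on 16³ grids for determinism and leakage checks, and
oracle suites of 50–100 random small instances per numerical contract.
These sizes make every property checkable on a laptop in minutes while
keeping each statistical property comfortably detectable.

## Known limitations

* Raw MKL weights are only comparable across sources of similar kernel
  scale; the weight table reports the scale for this reason.
* The per-fold correlation of 5–10 subjects is noisy by construction; the
  pooled-R diagnostic exists because of that, but the headline number
  remains the fold average, as the method defines it.
* With strong row normalization the model cannot represent overall lesion
  volume when lesions sit fully inside the mask; this is a property of
  the published standardization, preserved deliberately.
* Wilcoxon comparisons across folds treat folds as exchangeable units;
  with k = 10 per arm the exact test's resolution is limited (minimum
  two-sided p = 2/C(20,10) ≈ 1.1·10⁻⁵).
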