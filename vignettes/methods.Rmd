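---
title: "Multi-atlas labeling of functional ROIs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-atlas labeling of functional ROIs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The labeling problem

Functional regions of interest (fROIs) such as the occipital face area
(OFA) or posterior fusiform face area (pFFA) are defined per subject from
a localizer contrast, and their location and extent vary substantially
across individuals even after spatial normalization. `froimal` labels the
supra-threshold voxels of a new subject's Z-statistic map by combining
many manually labeled reference subjects (atlases), rather than one
group-level template, so that inter-individual variability is represented
in the references themselves.

The pipeline assumes its inputs are already on a single common grid
(bitwise-equal shape and affine); it performs no registration, smoothing
or intensity harmonization. Grid mismatches are always an error, never a
silent resample.

## Atlas encoding as a coordinate classifier

An atlas is not used as an image pair but distilled into a decision
forest from 0-based integer voxel coordinates $(x, y, z)$ to labels.
Training samples are the atlas's *candidate voxels* — activated
($Z > z_{thr}$, strict) and inside the *collective mask*, the union of
the modeled fROI labels over all atlases. Activated-but-unlabeled voxels
inside the mask are explicit background samples; this is what allows the
fused prediction to say "no fROI here".

Each tree is grown on a bootstrap resample (with replacement, same size
as the training set). At a node, one of the three coordinate axes is
drawn uniformly at random and the split threshold maximizing the
information gain (entropy impurity) is chosen among midpoints of
consecutive distinct values, ties resolved toward the lowest threshold.
Growth stops at the depth cap; minimum leaf size is 1 and there is no
pruning. Leaves store the class distribution of the samples they
received.

Numerical and degenerate-input choices:

* If the drawn axis is constant within a node, the remaining axes are
  tried in random order rather than forcing an impure leaf; a node whose
  samples share one coordinate becomes a leaf (it is necessarily pure in
  noiseless data, since one voxel carries one label). Forcing the leaf
  instead would only lower self-prediction fidelity without changing any
  interface.
* Voxel indices, not millimeter coordinates, are the features: axis-
  aligned splits are invariant under per-axis affine rescaling, so the
  two choices yield identical forests, and integer comparisons avoid
  floating-point threshold ties.
* Reproducibility: tree $t$ uses a private `splitmix64` stream seeded
  with `seed + t - 1`, so forests are independent of R's RNG state and
  identical across runs and platforms.
* Leaf voting: the field's forest implementations differ on whether a
  tree votes its leaf's full class distribution or only its modal class.
  The package averages class distributions (default `vote = "soft"`,
  smoother probability surfaces with T = 30 trees) and exposes
  `vote = "hard"` as an option.

Prediction pushes the target's candidate voxels through each selected
encoder, averages the per-class probabilities across atlases (classes
aligned over the experiment's full label set, missing classes at
probability 0), and takes the per-voxel argmax. Ties are resolved toward
background first, then the lowest label id — a deliberately conservative
rule under ambiguity. All non-candidate voxels are background. The target
side is mask-restricted symmetrically with training; whether that
restriction should apply at prediction time is genuinely open, and the
symmetric reading was chosen so that train- and test-time sample spaces
coincide.

Defaults T = 30 and D = 20 are the pipeline's operating point;
`forest_param_grid()` exists precisely to verify that accuracy is flat
over T, D ∈ [10, 40] on a given cohort (the acceptance suite checks a
spread below 0.05 on a low-variability cohort at T, D ∈ {10, 25, 40}).

## Atlas selection

Similarity between a target and an atlas is the Pearson correlation of
their Z values within the collective mask after clamping negative values
to zero — fROIs are defined by a positive contrast, so only the positive
pattern is informative. Clamping applies to both maps; a constant clamped
vector is assigned similarity 0 (lowest informative priority) with a
warning, rather than NaN. Rankings sort descending with ties broken by
subject id, so they are total and deterministic. The top N = 40 atlases
are fused by default; `n_selected_atlases = 0` means the whole database.

Normalized mutual information, $2I(X;Y)/(H(X)+H(Y))$ over equal-width
binned values, is available as an alternative metric. Binning uses 32
bins over the pooled range by default; whether to clamp before binning is
exposed (`nmi_clamp`, default TRUE for consistency with the Pearson
metric) because either reading is defensible.

## The GSS baseline

The single-atlas baseline builds, per fROI, the group probabilistic map
(voxelwise mean of binary indicators — exact rationals $k/n$), summarizes
the maps into a maximum probability map (MPM), and intersects the MPM
with the individual's supra-threshold activation. In the MPM,
probabilities strictly below the threshold are zeroed ("at least the
threshold" survives, so threshold 0 keeps every positive value), the
argmax over surviving fROIs is taken with ties toward the lowest label
id, and background arises only from the threshold — a background
probability map does not compete in the argmax. Reported GSS accuracy is
the mean across MPM thresholds {0, 0.1, 0.2}, since the threshold
controls the group-level region extent. GSS+AS applies exactly the same
mask, metric and N as the multi-atlas pathway, so any performance
difference is attributable to the atlas subset alone.

## Evaluation conventions

* **Dice.** `2|A∩B|/(|A|+|B|)`; both-empty pairs are *undefined* and
  excluded from averages (counting them as 1 would inflate scores for
  absent regions), one-empty pairs are 0.
* **Peak consistency.** The maximal-Z voxel of the automatic region must
  coincide with that of the manual region; the default radius of 0 mm is
  the strictest reading of a "matched" peak, and `peak_match_radius_mm`
  relaxes it. Argmax ties are broken by lexicographic voxel order.
* **LOSOCV.** Encoders are cached across folds — an encoder depends only
  on its own atlas, never on the fold composition — and a leakage guard
  asserts on every fold that the held-out subject is absent from the
  references. The collective mask is built once from the full database,
  matching how a deployed atlas database would define its spatial
  constraint.
* **Before/after-encoding pair similarity.** The prediction domain for
  the "after" labels is not dictated by the pipeline itself; the package
  predicts over the full collective mask (default) and offers the union
  of the two atlases' candidate sets as an alternative (`domain =
  "union"`).
* **Steiger's Z.** The one-common-index, pooled-estimate form: Fisher
  transforms of the two dependent correlations with the covariance
  correction $\psi/(1-\bar r^2)^2$, $\bar r = (r_{12}+r_{13})/2$.
  Correlations of exactly ±1 give an infinite statistic. The acceptance
  suite verifies empirical type-I error in [0.04, 0.06] at α = 0.05
  under a trivariate normal null (n = 50, 5000 draws).

## The synthetic cohort generator

Real manually labeled fROI databases are not redistributable, so the
package validates on generated cohorts. Each subject's fROIs are
ellipsoids displaced by a per-axis normal translation, rescaled radially,
and perturbed at the boundary by a smoothed random field added to the
normalized radius; overlapping regions resolve to the smaller normalized
radius. The Z map is smoothed background noise plus a per-region bump
that peaks at the displaced center (`peak ~ N(z_peak_mean, z_peak_sd)`)
and decays linearly in normalized radius to 2.3 at the boundary — so the
supra-threshold set approximately, but not exactly, matches the ground
truth, reproducing the label/activation mismatch present in real data.
Atlas labels are the ground truth restricted to supra-threshold voxels,
upholding the atlas contract by construction. With `n_prototypes > 1`,
templates are first shifted by fixed per-prototype offsets and each
subject draws a prototype, creating latent subgroups in which
activation-pattern similarity genuinely predicts label-transfer quality —
the property atlas selection needs to be demonstrably useful.

Defaults, chosen once as plausible for small cortical fROIs on a 2 mm
grid and not tuned thereafter: grid 32×38×28 voxels; two templates with
7–8 mm semi-axes separated by ≈ 20 mm; `translation_sd_mm = 3`;
`scale_sd = 0.1`; `shape_jitter_sd = 0.15`; smoothing FWHM 6 mm; peak
Z ~ N(5.0, 0.8) (clipped at 2.5); background noise SD 1.0; prototype
offset SD 6 mm. The `prototype_offset_sd_mm` parameter exists because the
magnitude of subgroup separation must be controllable for the
within-versus-between-prototype similarity contrast to be a testable
property.

What the generator does *not* emulate: cortical geometry and folding,
spatially correlated anatomy across regions, registration error,
inter-subject intensity scaling, or any BOLD/GLM structure — it produces
statistical maps only. Passing tests therefore demonstrate the
correctness and qualitative behavior of the algorithms (encoding beats
direct transfer under displacement; similarity rank predicts transfer
quality; selection helps at intermediate subset sizes), not quantitative
accuracy on any real dataset.

## Problem sizes

The validation suite runs at desk scale, chosen so a full run completes
in minutes on one CPU: a 10-subject zero-variability cohort for recovery
and parameter-insensitivity checks; a 60-subject clustered cohort
(translation SD 4 mm, 2 prototypes) for the encoding, selection and
sweep experiments (counts {1, 5, 10, 20, 40} with 3 random repeats);
5000 Monte-Carlo draws for the Steiger calibration. The same conditions
are re-executed from scratch by `scripts/acceptance.R`.

## Known limitations

* Voxelwise majority fusion only; globally or locally weighted voting
  and patch-based fusion are out of scope, as are classifiers other than
  the decision forest and hyperalignment-based similarity metrics.
* No surface (GIFTI) support; volumes only, one grid per experiment.
* The forest uses coordinates alone — no Z values or richer local
  features — by design; cohorts whose label boundaries are driven by
  intensity rather than location will not benefit from the encoding.
* Encoder JSON serialization favors portability and inspectability over
  compactness; very deep forests on large sample sets produce large
  files.
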