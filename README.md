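# froimal — multi-atlas labeling of subject-specific functional ROIs

`froimal` automatically identifies subject-specific functional regions of
interest (fROIs) — regions defined in each individual by their functional
response, such as the face-selective OFA and pFFA — in thresholded fMRI
activation maps. Manual fROI delineation by experts is accurate but slow
and knowledge-intensive; `froimal` replaces it with a multi-atlas labeling
(MAL) pipeline for activation volumes already normalized to a common
stereotaxic grid (e.g. MNI space).

## Method

Given a database of reference *atlases* — pairs of a Z-statistic
activation map and its manually labeled fROI volume — and an unlabeled
target map, the pipeline is:

1. **Collective mask.** The union of the requested fROI labels across all
   atlases constrains the candidate voxels. Candidates are voxels with
   `Z > 2.3` (p < 0.01 uncorrected, strict inequality) inside the mask.
2. **Atlas encoding.** Each atlas is distilled into a decision forest
   that maps a voxel coordinate `(x, y, z)` to a label probability
   vector over {background, fROI₁, …, fROI_K}. Each of the T = 30 trees
   is grown on a bootstrap resample of the atlas's candidate voxels,
   splitting one randomly drawn coordinate axis per node by maximal
   information gain, to depth D = 20. Because only coordinates are
   features, the forest captures the spatial extent of a delineation as
   a set of probabilistic rules instead of a rigid voxel-to-voxel
   correspondence.
3. **Atlas selection.** Atlases are ranked by the similarity of their
   positive activation pattern to the target — Pearson correlation of
   the negative-clamped Z values within the mask (normalized mutual
   information is available as an alternative) — and the top N = 40 are
   retained.
4. **Label fusion.** The selected encoders each predict a probabilistic
   label map for the target's candidate voxels; the maps are averaged
   and a majority (argmax) vote yields the final labels, with ties
   resolved toward background, then the lowest label id.

Accuracy against manual labels is measured by Dice overlap,
`2|A∩B|/(|A|+|B|)`, and by peak-location consistency. Two baselines are
included: *image-based transfer* (direct label propagation assuming
one-to-one voxel correspondence, averaged and voted identically) and the
single-atlas *GSS* method (group probabilistic maps → maximum probability
map at thresholds {0, 0.1, 0.2} → intersection with the individual's
supra-threshold activation), optionally with the same atlas selection
(GSS+AS). Mean-intensity concordance between automatic and manual regions
is compared across methods with Steiger's Z test for dependent
correlations.

Because manually labeled atlas databases are not redistributable, the
package ships a synthetic cohort generator (`population_spec()`,
`generate_population()`) producing Z-maps with ellipsoidal fROIs that
vary in location, extent and shape across subjects — optionally in latent
subgroups — together with ground-truth labels, so the whole pipeline is
testable end to end.

## Worked example

```r
library(froimal)

# cohort of 20 synthetic subjects with realistic variability
pop <- generate_population(population_spec(n_subjects = 20,
                                           translation_sd_mm = 3, seed = 1))
population_variability_report(pop$db, pop$ground_truth)
#>   roi_label mean_pairwise_dice centroid_dispersion_mm volume_cv
#> 1         1          0.3024385               5.282161 0.2584701
#> 2         2          0.3758112               4.373144 0.2951090

cfg    <- experiment_config(n_selected_atlases = 10)
target <- pop$db$atlases[["sub020"]]
refs   <- atlas_db(pop$db$atlases[1:19])
auto   <- mal_label_subject(target$activation, refs, labels = c(1, 2), cfg)
for (l in 1:2) cat(sprintf("ROI %d Dice vs manual: %.3f\n", l,
  dice_coefficient(label_voxels(auto, l), label_voxels(target$labels, l))))
#> ROI 1 Dice vs manual: 0.936
#> ROI 2 Dice vs manual: 0.991

rec <- losocv(pop$db, c(1, 2), cfg, methods = c("mal", "gss_as"))
aggregate(cbind(dice, peak_match) ~ method, rec, mean)
#>   method      dice peak_match
#> 1 gss_as 0.8959864      0.975
#> 2    mal 0.9852762      1.000
```

The variability report shows that the raw manual labels overlap poorly
across subjects (mean pairwise Dice ≈ 0.3, centroids dispersed ≈ 5 mm) —
exactly the situation in which direct label transfer fails — while the
multi-atlas pipeline recovers the held-out subject's regions with Dice
above 0.93, and beats the single-atlas GSS+AS baseline under
leave-one-subject-out cross-validation.

Real data enter as NIfTI volumes: `read_activation_map()` /
`read_label_map()` (with a JSON sidecar for label names), and results
leave as integer NIfTI plus sidecar via `write_label_map()`.

## Command line

A thin launcher `exec/froimal` exposes the pipeline as subcommands:

```sh
froimal simulate --out cohort --n_subjects 20 --seed 1
froimal label    --db cohort --target sub020 --out sub020_froi.nii.gz --n_atlases 10
froimal evaluate --db cohort --out records.csv --methods mal,gss_as
```

Every artifact carries a sidecar with the resolved configuration hash and
seed; identical invocations produce bitwise-identical outputs.

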