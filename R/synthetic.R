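# Synthetic activation-map cohorts. Real functional atlas databases of
# manually delineated fROIs are not redistributable, so validation runs
# on generated populations: ellipsoidal "fROIs" whose location, extent
# and boundary vary across subjects, with Z bumps decaying from a random
# peak at the displaced center to the activation threshold (2.3) at the
# region boundary, on top of smoothed Gaussian background noise.
# Optional latent prototypes create subgroups so that activation-pattern
# similarity genuinely predicts label-transfer quality.

#' ROI template
#'
#' @param label positive integer label id (unique within a spec).
#' @param center_mm world-space center of the ellipsoid (mm).
#' @param radii_mm ellipsoid semi-axes (mm), all positive.
#' @param name region name.
#' @return A `roi_template`.
#' @export
roi_template <- function(label, center_mm, radii_mm, name = NULL) {
  label <- as.integer(label)
  if (is.na(label) || label < 1L) stop("'label' must be a positive integer")
  center_mm <- as.numeric(center_mm); radii_mm <- as.numeric(radii_mm)
  if (length(center_mm) != 3 || length(radii_mm) != 3 || any(radii_mm <= 0))
    stop("center and radii must be positive length-3 mm vectors")
  if (is.null(name)) name <- paste0("roi", label)
  structure(list(label = label, center_mm = center_mm, radii_mm = radii_mm,
                 name = as.character(name)),
            class = "roi_template")
}

# two well-separated ventral blobs on the default 2 mm grid, sized like
# small cortical face-selective regions
default_roi_templates <- function() {
  list(roi_template(1L, c(22, 24, 20), c(7, 7, 6), "synOFA"),
       roi_template(2L, c(28, 48, 18), c(8, 7, 6), "synFFA"))
}

#' Synthetic population specification
#'
#' Describes a cohort of Z-statistic maps with ground-truth fROI labels.
#' Per subject and ROI, the template ellipsoid is displaced by a random
#' translation, rescaled radially, and its boundary is perturbed by a
#' smoothed random field; the Z bump peaks at the displaced center
#' (`peak ~ Normal(z_peak_mean, z_peak_sd)`) and decays linearly in
#' normalized ellipsoid radius to 2.3 at the boundary, on top of
#' smoothed background noise, so that the supra-threshold set tracks -
#' but does not exactly equal - the ground truth, as in real data. With
#' `n_prototypes > 1`, templates are first shifted by fixed per-prototype
#' offsets and each subject draws one prototype, creating latent
#' subgroups.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param grid_shape integer triple, default `c(32, 38, 28)` voxels at
#'   2 mm spacing.
#' @param rois list of [roi_template()] objects.
#' @param translation_sd_mm per-axis SD of the random ROI translation.
#' @param scale_sd SD of the radial scale factor about 1.
#' @param shape_jitter_sd SD of the boundary jitter, in units of
#'   normalized ellipsoid radius.
#' @param n_prototypes number of latent subgroups (>= 1).
#' @param prototype_offset_sd_mm per-axis SD of the fixed prototype
#'   offsets (used only when `n_prototypes > 1`).
#' @param noise_smoothing_fwhm_mm FWHM of the Gaussian smoothing applied
#'   to the background-noise and jitter fields.
#' @param z_peak_mean mean peak Z of an ROI bump (default 5.0).
#' @param z_peak_sd SD of the peak Z across subjects.
#' @param background_noise_sd marginal SD of the background noise field
#'   (default 1.0).
#' @param seed integer seed; generation is fully deterministic given it.
#' @return A `population_spec`.
#' @export
population_spec <- function(n_subjects,
                            grid_shape = c(32L, 38L, 28L),
                            rois = default_roi_templates(),
                            translation_sd_mm = 3,
                            scale_sd = 0.1,
                            shape_jitter_sd = 0.15,
                            n_prototypes = 1L,
                            prototype_offset_sd_mm = 6,
                            noise_smoothing_fwhm_mm = 6,
                            z_peak_mean = 5.0,
                            z_peak_sd = 0.8,
                            background_noise_sd = 1.0,
                            seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 2L) stop("'n_subjects' must be >= 2")
  stopifnot(all(vapply(rois, inherits, logical(1), "roi_template")))
  labs <- vapply(rois, `[[`, integer(1), "label")
  if (anyDuplicated(labs)) stop("ROI labels must be unique")
  sds <- c(translation_sd_mm, scale_sd, shape_jitter_sd,
           prototype_offset_sd_mm, noise_smoothing_fwhm_mm, z_peak_sd,
           background_noise_sd)
  if (any(sds < 0)) stop("spread parameters must be >= 0")
  n_prototypes <- as.integer(n_prototypes)
  if (is.na(n_prototypes) || n_prototypes < 1L)
    stop("'n_prototypes' must be >= 1")
  grid <- vol_grid(grid_shape, id = "synthetic")
  extent <- (grid$shape - 1) * 2  # mm, 2 mm spacing at the origin
  for (r in rois) {
    reach <- r$radii_mm + 3 * translation_sd_mm +
      if (n_prototypes > 1L) 3 * prototype_offset_sd_mm else 0
    if (any(r$center_mm - reach < 0) || any(r$center_mm + reach > extent))
      warning(sprintf(
        "ROI '%s' may be clipped at the grid boundary after displacement",
        r$name))
  }
  structure(list(n_subjects = n_subjects, grid = grid, rois = rois,
                 translation_sd_mm = translation_sd_mm, scale_sd = scale_sd,
                 shape_jitter_sd = shape_jitter_sd,
                 n_prototypes = n_prototypes,
                 prototype_offset_sd_mm = prototype_offset_sd_mm,
                 noise_smoothing_fwhm_mm = noise_smoothing_fwhm_mm,
                 z_peak_mean = z_peak_mean, z_peak_sd = z_peak_sd,
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "population_spec")
}

# separable Gaussian smoothing; per-row normalized kernels avoid edge
# attenuation
gauss_smooth <- function(arr, sigma_vox) {
  d <- dim(arr)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    n <- d[ax]
    idx <- seq_len(n)
    K <- exp(-outer(idx, idx, "-")^2 / (2 * s^2))
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    arr <- aperm(arr, perm)
    dp <- dim(arr)
    arr <- array(K %*% matrix(arr, nrow = n), dp)
    arr <- aperm(arr, order(perm))
  }
  arr
}

smoothed_unit_field <- function(shape, fwhm_mm, spacing_mm = 2) {
  f <- array(rnorm(prod(shape)), shape)
  if (fwhm_mm > 0) {
    sigma <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing_mm
    f <- gauss_smooth(f, rep(sigma, 3))
  }
  s <- sd(as.vector(f))
  if (s > 0) f <- f / s
  f
}

#' Generate a synthetic atlas database with ground truth
#'
#' Draws the cohort described by a [population_spec()]: per subject, a
#' Z-statistic [activation_map()], the unrestricted ground-truth
#' [label_map()], and the [atlas()] whose labels are the ground truth
#' restricted to supra-threshold voxels (the atlas contract). Fully
#' deterministic given `spec$seed`; the caller's RNG state is left
#' untouched.
#'
#' @param spec a [population_spec()].
#' @return List with `db` (an [atlas_db()]) and `ground_truth` (named
#'   list of [label_map()] per subject).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "population_spec"))
  with_seed(spec$seed, generate_population_impl(spec))
}

generate_population_impl <- function(spec) {
  grid <- spec$grid
  n_vox <- prod(grid$shape)
  mm <- voxel_to_mm(grid, voxel_coords(grid, seq_len(n_vox)))
  K <- length(spec$rois)
  label_names <- setNames(vapply(spec$rois, `[[`, character(1), "name"),
                          vapply(spec$rois, function(r)
                            as.character(r$label), character(1)))
  proto_offsets <- array(0, c(spec$n_prototypes, K, 3))
  if (spec$n_prototypes > 1L)
    proto_offsets[] <- rnorm(spec$n_prototypes * K * 3,
                             sd = spec$prototype_offset_sd_mm)
  atlases <- vector("list", spec$n_subjects)
  truth <- vector("list", spec$n_subjects)
  ids <- sprintf("sub%03d", seq_len(spec$n_subjects))
  for (s in seq_len(spec$n_subjects)) {
    proto <- if (spec$n_prototypes > 1L)
      sample.int(spec$n_prototypes, 1L) else 1L
    r_eff <- matrix(NA_real_, n_vox, K)
    bump <- numeric(n_vox)
    for (k in seq_len(K)) {
      roi <- spec$rois[[k]]
      center <- roi$center_mm + proto_offsets[proto, k, ] +
        rnorm(3, sd = spec$translation_sd_mm)
      scale <- max(0.2, rnorm(1, mean = 1, sd = spec$scale_sd))
      peak <- max(2.5, rnorm(1, mean = spec$z_peak_mean,
                             sd = spec$z_peak_sd))
      r <- sqrt(colSums((t(mm) - center)^2 / (roi$radii_mm * scale)^2))
      if (spec$shape_jitter_sd > 0) {
        J <- smoothed_unit_field(grid$shape, spec$noise_smoothing_fwhm_mm)
        r <- r + spec$shape_jitter_sd * as.vector(J)
      }
      r_eff[, k] <- r
      inside <- r <= 1
      bump[inside] <- pmax(bump[inside],
                           2.3 + (peak - 2.3) * (1 - r[inside]))
    }
    lab <- integer(n_vox)
    any_inside <- which(rowSums(r_eff <= 1) > 0)
    if (length(any_inside) > 0) {
      # overlapping ROIs resolve to the smaller normalized radius
      kk <- max.col(-r_eff[any_inside, , drop = FALSE],
                    ties.method = "first")
      lab[any_inside] <- vapply(spec$rois, `[[`, integer(1),
                                "label")[kk]
    }
    if (length(any_inside) == 0)
      stop(sprintf("subject %s: every ROI escaped the grid", ids[s]))
    noise <- numeric(n_vox)
    if (spec$background_noise_sd > 0)
      noise <- spec$background_noise_sd *
        as.vector(smoothed_unit_field(grid$shape,
                                      spec$noise_smoothing_fwhm_mm))
    z <- array(bump + noise, grid$shape)
    act <- activation_map(grid, z, ids[s])
    tr <- label_map(grid, array(lab, grid$shape),
                    label_names = label_names, subject_id = ids[s])
    truth[[s]] <- tr
    atlases[[s]] <- atlas(act, tr, z_threshold = 2.3, quiet = TRUE)
  }
  names(truth) <- ids
  list(db = atlas_db(atlases), ground_truth = truth)
}

#' Variability report for a synthetic population
#'
#' Quantifies inter-subject variability of each ROI in the ground-truth
#' labels: mean pairwise Dice, centroid dispersion (root mean squared
#' distance of per-subject centroids from their grand mean, mm), and
#' volume coefficient of variation.
#'
#' @param db an [atlas_db()] (used for the grid).
#' @param ground_truth named list of [label_map()] per subject.
#' @return Data.frame with one row per ROI: `roi_label`,
#'   `mean_pairwise_dice`, `centroid_dispersion_mm`, `volume_cv`.
#' @export
population_variability_report <- function(db, ground_truth) {
  labels <- sort(unique(unlist(lapply(ground_truth, function(t)
    setdiff(unique(as.vector(t$labels)), 0L)))))
  grid <- db$grid
  rows <- lapply(labels, function(l) {
    sets <- lapply(ground_truth, label_voxels, label = l)
    nonempty <- sets[vapply(sets, length, integer(1)) > 0]
    pair_d <- c()
    if (length(nonempty) >= 2) {
      n <- length(nonempty)
      for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
        pair_d <- c(pair_d, dice_coefficient(nonempty[[i]], nonempty[[j]]))
    }
    cents <- t(vapply(nonempty, function(v)
      colMeans(voxel_to_mm(grid, voxel_coords(grid, v))), numeric(3)))
    disp <- if (nrow(cents) >= 2)
      sqrt(mean(rowSums(sweep(cents, 2, colMeans(cents))^2))) else 0
    vols <- vapply(nonempty, length, integer(1))
    data.frame(roi_label = l,
               mean_pairwise_dice = if (length(pair_d)) mean(pair_d) else NA,
               centroid_dispersion_mm = disp,
               volume_cv = if (mean(vols) > 0) sd(vols) / mean(vols) else NA)
  })
  do.call(rbind, rows)
}
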