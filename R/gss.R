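# Single-atlas (GSS) baseline: group probabilistic maps -> maximum
# probability map (MPM) -> intersection with the individual's
# supra-threshold activation; optionally preceded by atlas selection
# (GSS+AS) using the same mask, metric and N as the multi-atlas pathway.

#' Group probabilistic maps of fROIs
#'
#' For each label, the voxelwise mean of the per-atlas binary indicator
#' volumes: the likelihood that a voxel belongs to that fROI across the
#' group. Values are exact rationals k/n where n is the number of
#' contributing atlases.
#'
#' @param atlases nonempty list of [atlas()] objects on one grid.
#' @param labels integer vector of fROI label ids.
#' @return Named list (by label id) of numeric 3D probability arrays.
#' @export
build_probabilistic_maps <- function(atlases, labels) {
  if (length(atlases) == 0) stop("empty atlas list")
  labels <- sort(unique(as.integer(labels)))
  g <- atlases[[1]]$labels$grid
  out <- lapply(labels, function(l) {
    acc <- array(0, g$shape)
    for (a in atlases) {
      stop_if_grid_mismatch(g, a$labels$grid, "atlases")
      acc <- acc + (a$labels$labels == l)
    }
    acc / length(atlases)
  })
  names(out) <- as.character(labels)
  out
}

#' Maximum probability map
#'
#' Per voxel, probabilities strictly below `threshold` are zeroed; if any
#' survive, the voxel is assigned the label with the highest surviving
#' probability (ties toward the lowest label id), otherwise background.
#' At threshold 0 every voxel with any positive probability receives the
#' plain argmax label. Background does not compete in the argmax: the
#' threshold alone creates background.
#'
#' @param prob_maps named list of probability arrays from
#'   [build_probabilistic_maps()].
#' @param threshold probability threshold in \[0, 1\].
#' @param grid the [vol_grid()] of the experiment.
#' @param label_names optional label names.
#' @return A [label_map()].
#' @export
build_mpm <- function(prob_maps, threshold, grid, label_names = NULL) {
  if (threshold < 0 || threshold > 1) stop("'threshold' must be in [0, 1]")
  labels <- as.integer(names(prob_maps))
  shp <- dim(prob_maps[[1]])
  for (p in prob_maps)
    if (!identical(dim(p), shp)) stop("inconsistent grids across prob_maps")
  if (!identical(as.integer(shp), grid$shape))
    stop("prob_maps do not match the grid")
  n <- prod(shp)
  best_p <- numeric(n)
  best_l <- integer(n)   # 0 = background
  for (i in order(labels)) {           # ascending id => ties keep lowest
    p <- as.vector(prob_maps[[i]])
    p[p < threshold] <- 0
    take <- p > 0 & p > best_p
    best_p[take] <- p[take]
    best_l[take] <- labels[i]
  }
  label_map(grid, array(best_l, shp), label_names = label_names)
}

#' Label a subject with the GSS baseline
#'
#' Builds the group probabilistic maps (optionally from the top-N most
#' similar atlases: GSS+AS), forms the MPM at the given threshold, and
#' intersects it with the target's supra-threshold activation: the output
#' carries label l exactly where MPM = l and target Z > z_threshold.
#'
#' @param target an [activation_map()] (excluded from `atlases`).
#' @param atlases list of reference [atlas()] objects.
#' @param labels integer vector of fROI label ids.
#' @param cfg an [experiment_config()].
#' @param threshold MPM probability threshold.
#' @param use_selection apply atlas selection before building the group
#'   maps (GSS+AS), with the same mask, metric and N as the multi-atlas
#'   pathway.
#' @param mask optional precomputed `collective_mask` (needed only when
#'   `use_selection = TRUE`; rebuilt if NULL).
#' @param label_names optional label names for the output.
#' @return A [label_map()].
#' @export
gss_label_subject <- function(target, atlases, labels,
                              cfg = experiment_config(), threshold = 0,
                              use_selection = FALSE, mask = NULL,
                              label_names = NULL) {
  ids <- vapply(atlases, `[[`, character(1), "subject_id")
  if (target$subject_id %in% ids)
    stop(sprintf("target subject '%s' is present in the atlas list (leakage)",
                 target$subject_id))
  if (use_selection) {
    db <- atlas_db(atlases)
    if (is.null(mask)) mask <- build_collective_mask(db, labels)
    ranked <- rank_atlases(target, db, mask, cfg)
    keep <- select_atlases(ranked, min(cfg$n_selected_atlases, length(atlases)))
    atlases <- db$atlases[keep]
  }
  pm <- build_probabilistic_maps(atlases, labels)
  mpm <- build_mpm(pm, threshold, target$grid, label_names = label_names)
  out <- mpm$labels
  out[!(target$values > cfg$z_threshold)] <- 0L
  label_map(target$grid, out, label_names = label_names,
            subject_id = target$subject_id)
}

#' GSS accuracy averaged over MPM thresholds
#'
#' Runs [gss_label_subject()] at each configured MPM threshold, scores
#' the per-fROI Dice overlap against the manual labels, and returns the
#' across-threshold mean per fROI (the convention under which the
#' baseline's accuracy is reported).
#'
#' @param target an [activation_map()].
#' @param manual the target's manual [label_map()] (gold standard).
#' @param atlases list of reference [atlas()] objects.
#' @param labels integer vector of fROI label ids.
#' @param cfg an [experiment_config()]; supplies `mpm_thresholds`.
#' @param use_selection GSS+AS toggle.
#' @param mask optional precomputed mask for selection.
#' @return Data.frame with columns `roi_label`, `dice` (mean across
#'   thresholds; NA if undefined at every threshold).
#' @export
gss_multi_threshold_accuracy <- function(target, manual, atlases, labels,
                                         cfg = experiment_config(),
                                         use_selection = FALSE,
                                         mask = NULL) {
  labels <- sort(unique(as.integer(labels)))
  per_thr <- lapply(cfg$mpm_thresholds, function(thr) {
    auto <- gss_label_subject(target, atlases, labels, cfg, thr,
                              use_selection = use_selection, mask = mask)
    vapply(labels, function(l)
      dice_coefficient(label_voxels(auto, l), label_voxels(manual, l)),
      numeric(1))
  })
  mat <- do.call(rbind, per_thr)   # thresholds x labels
  d <- colMeans(mat, na.rm = TRUE)
  d[is.nan(d)] <- NA_real_
  data.frame(roi_label = labels, dice = unname(d))
}
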