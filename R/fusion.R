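# Label fusion: average per-atlas probabilistic predictions and take the
# per-voxel majority (argmax) vote. Also the image-based direct-transfer
# baseline, in which each atlas contributes the one-hot vector of its own
# label at each target voxel instead of a forest prediction.

align_classes <- function(maps) {
  classes <- sort(unique(unlist(lapply(maps, `[[`, "classes"))))
  classes <- c(0L, setdiff(classes, 0L))
  classes
}

#' Fuse probabilistic label maps by averaging
#'
#' Voxelwise arithmetic mean of the aligned per-class probabilities.
#' Class lists are unioned; a class missing from one map contributes
#' probability 0 there. The evaluated domain is the union of the input
#' domains (a voxel outside a map's domain contributes that map's
#' implicit degenerate background vector).
#'
#' @param maps nonempty list of [prob_label_map()] objects on one grid.
#' @return A fused [prob_label_map()].
#' @export
fuse_prob_maps <- function(maps) {
  if (length(maps) == 0) stop("cannot fuse an empty list of maps")
  stopifnot(all(vapply(maps, inherits, logical(1), "prob_label_map")))
  g <- maps[[1]]$grid
  for (m in maps) stop_if_grid_mismatch(g, m$grid, "probability maps")
  classes <- align_classes(maps)
  vox <- sort(unique(unlist(lapply(maps, `[[`, "voxels"))))
  acc <- matrix(0, length(vox), length(classes))
  for (m in maps) {
    contrib <- matrix(0, length(vox), length(classes))
    contrib[, 1] <- 1  # implicit background outside m's domain
    if (length(m$voxels) > 0) {
      rows <- match(m$voxels, vox)
      contrib[rows, ] <- 0
      contrib[rows, match(m$classes, classes)] <- m$probs
    }
    acc <- acc + contrib
  }
  prob_label_map(g, classes, vox, acc / length(maps),
                 maps[[1]]$subject_id)
}

#' Majority vote on a fused probabilistic map
#'
#' Assigns each evaluated voxel the class with maximal averaged
#' probability. Ties are broken toward background first, then toward the
#' lowest label id - a conservative rule that prefers "no fROI" under
#' ambiguity. Voxels outside the evaluated domain are background.
#'
#' @param fused a [prob_label_map()].
#' @param label_names optional named character vector of label names.
#' @return A [label_map()].
#' @export
majority_vote <- function(fused, label_names = NULL) {
  stopifnot(inherits(fused, "prob_label_map"))
  lab <- array(0L, fused$grid$shape)
  if (length(fused$voxels) > 0) {
    # classes are ordered background-first then ascending label id, so
    # the first maximum implements the documented tie-break
    win <- apply(fused$probs, 1, which.max)
    lab[fused$voxels] <- fused$classes[win]
  }
  label_map(fused$grid, lab, label_names = label_names,
            subject_id = fused$subject_id)
}

#' Image-based label transfer baseline
#'
#' The traditional encoding scheme: labels are transferred from each
#' atlas to the target under the assumption of one-to-one voxel
#' correspondence in stereotaxic space. At every target candidate voxel
#' each atlas contributes the one-hot vector of its own label there
#' (background where unlabeled); the vectors are averaged and
#' majority-voted exactly as in the forest pathway.
#'
#' @param atlases nonempty list of [atlas()] objects.
#' @param target an [activation_map()].
#' @param mask the experiment's `collective_mask`.
#' @param cfg an [experiment_config()].
#' @param labels integer vector of fROI labels being transferred.
#' @return A [label_map()].
#' @export
image_based_transfer <- function(atlases, target, mask,
                                 cfg = experiment_config(), labels) {
  if (length(atlases) == 0) stop("empty atlas subset")
  maps <- lapply(atlases, function(a)
    one_hot_transfer(a, target, mask, cfg, labels))
  majority_vote(fuse_prob_maps(maps))
}

# one atlas's contribution to the image-based baseline
one_hot_transfer <- function(a, target, mask, cfg, labels) {
  stop_if_grid_mismatch(a$labels$grid, target$grid, "atlas and target")
  labels <- sort(unique(as.integer(labels)))
  classes <- c(0L, labels)
  vox <- candidate_voxels(target, mask, cfg$z_threshold)
  lab_at <- as.vector(a$labels$labels)[vox]
  lab_at[!(lab_at %in% labels)] <- 0L
  probs <- matrix(0, length(vox), length(classes))
  if (length(vox) > 0)
    probs[cbind(seq_along(vox), match(lab_at, classes))] <- 1
  prob_label_map(target$grid, classes, vox, probs, target$subject_id)
}

#' Label a new subject by multi-atlas labeling
#'
#' The end-to-end pipeline: build the collective mask over the requested
#' labels, rank the database by activation-pattern similarity to the
#' target, select the top-N atlases, train (or reuse) their encoders,
#' predict a probabilistic map from each, average, and majority-vote.
#' Deterministic given the config seed.
#'
#' @param target an [activation_map()] for the unlabeled subject (its
#'   subject id must not occur in `db`).
#' @param db an [atlas_db()] of reference atlases.
#' @param labels integer vector of fROI label ids to identify.
#' @param cfg an [experiment_config()].
#' @param mask optional precomputed `collective_mask` (rebuilt if NULL).
#' @param encoders optional named list of precomputed `encoded_atlas`
#'   objects keyed by subject id (an atlas's encoder does not depend on
#'   the target, so encoders can be cached across targets).
#' @param label_names optional label names for the output map.
#' @return A [label_map()] of the fused, voted fROI assignment.
#' @export
mal_label_subject <- function(target, db, labels, cfg = experiment_config(),
                              mask = NULL, encoders = NULL,
                              label_names = NULL) {
  stopifnot(inherits(db, "atlas_db"))
  if (cfg$n_selected_atlases > length(db$atlases))
    stop(sprintf("n_selected_atlases (%d) exceeds database size (%d)",
                 cfg$n_selected_atlases, length(db$atlases)))
  if (is.null(mask)) mask <- build_collective_mask(db, labels)
  ranked <- rank_atlases(target, db, mask, cfg)
  chosen <- select_atlases(ranked, cfg$n_selected_atlases)
  maps <- lapply(chosen, function(id) {
    enc <- if (!is.null(encoders) && id %in% names(encoders)) encoders[[id]]
           else train_atlas_encoder(db$atlases[[id]], mask, labels, cfg)
    predict_prob_map(enc, target, mask, cfg, labels = labels)
  })
  majority_vote(fuse_prob_maps(maps), label_names = label_names)
}
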