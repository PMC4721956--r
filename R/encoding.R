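#' Encode an atlas as a coordinate-to-label decision forest
#'
#' Distills one reference atlas into a classifier from 0-based voxel
#' coordinates (x, y, z) to fROI labels. Training samples are the atlas's
#' candidate voxels (activated, `Z > z_threshold`, inside the collective
#' mask); the target class is the atlas label there, with
#' activated-but-unlabeled voxels serving as explicit background samples.
#' Each of the `n_trees` trees is grown on a bootstrap resample (with
#' replacement, same size); at every node a single coordinate axis is
#' drawn at random and split to maximize information gain (entropy
#' impurity), down to `max_depth`, minimum leaf size 1. Only coordinates
#' are used as features - no Z values and no appearance features - so the
#' encoder captures the spatial extent of the delineation, not its
#' intensity profile.
#'
#' @param atlas an [atlas()].
#' @param mask the [build_collective_mask()] of the experiment.
#' @param labels integer vector of fROI label ids being modeled; the
#'   encoder's class list is `c(0, sort(labels))`.
#' @param cfg an [experiment_config()]; supplies `z_threshold` and the
#'   forest parameters.
#' @return An `encoded_atlas` with fields `forest`, `classes`, `params`,
#'   `source_subject_id`, `n_samples`.
#' @export
train_atlas_encoder <- function(atlas, mask, labels, cfg = experiment_config()) {
  stopifnot(inherits(atlas, "atlas"), inherits(mask, "collective_mask"))
  stop_if_grid_mismatch(atlas$activation$grid, mask$grid, "atlas and mask")
  labels <- sort(unique(as.integer(labels)))
  if (any(labels <= 0)) stop("label ids must be positive")
  vox <- candidate_voxels(atlas$activation, mask, cfg$z_threshold)
  if (length(vox) == 0)
    stop(sprintf("atlas '%s' has no candidate voxels to train on",
                 atlas$subject_id))
  classes <- c(0L, labels)
  y_raw <- as.vector(atlas$labels$labels)[vox]
  y_raw[!(y_raw %in% labels)] <- 0L           # outside the modeled label set
  y <- match(y_raw, classes) - 1L             # 0-based class index
  X <- voxel_coords(atlas$activation$grid, vox)
  forest <- .df_train(X, y, length(classes), cfg$forest$n_trees,
                      cfg$forest$max_depth, as.double(cfg$forest$seed))
  structure(list(forest = forest, classes = classes, params = cfg$forest,
                 source_subject_id = atlas$subject_id,
                 n_samples = length(vox)),
            class = "encoded_atlas")
}

#' @export
print.encoded_atlas <- function(x, ...) {
  cat(sprintf("<encoded_atlas '%s'> %d trees, depth <= %d, %d classes, %d samples\n",
              x$source_subject_id, x$params$n_trees, x$params$max_depth,
              length(x$classes), x$n_samples))
  invisible(x)
}

#' Predict a probabilistic label map for a target subject
#'
#' Pushes the target's candidate voxels through one trained encoder. Under
#' soft voting (default) each tree contributes the class distribution of
#' the leaf the voxel reaches and the contributions are averaged; under
#' hard voting each tree casts one vote for its leaf's modal class. All
#' non-candidate voxels receive the degenerate background vector. The
#' output class list is `c(0, sort(labels))` for the experiment's full
#' label set; classes unknown to this encoder get probability 0.
#'
#' @param enc an `encoded_atlas`.
#' @param target an [activation_map()].
#' @param mask the experiment's `collective_mask`.
#' @param cfg an [experiment_config()].
#' @param labels optional experiment label set; defaults to the encoder's.
#' @return A [prob_label_map()].
#' @export
predict_prob_map <- function(enc, target, mask, cfg = experiment_config(),
                             labels = NULL) {
  stopifnot(inherits(enc, "encoded_atlas"), inherits(target, "activation_map"))
  stop_if_grid_mismatch(target$grid, mask$grid, "target and mask")
  if (is.null(labels)) labels <- setdiff(enc$classes, 0L)
  classes <- c(0L, sort(unique(as.integer(labels))))
  vox <- candidate_voxels(target, mask, cfg$z_threshold)
  if (length(vox) == 0)
    return(prob_label_map(target$grid, classes, integer(0),
                          matrix(0, 0, length(classes)), target$subject_id))
  X <- voxel_coords(target$grid, vox)
  raw <- .df_predict(enc$forest, X, length(enc$classes), cfg$vote == "hard")
  probs <- matrix(0, nrow(raw), length(classes))
  probs[, match(enc$classes, classes)] <- raw
  prob_label_map(target$grid, classes, vox, probs, target$subject_id)
}

#' Serialize an encoded atlas to a portable JSON file
#'
#' The file carries a versioned header, the forest parameters, the class
#' list and the full structure of every tree, so an encoder can be
#' trained once and reused across experiments.
#'
#' @param enc an `encoded_atlas`.
#' @param path output path (conventionally `<subject>.encoder.json`).
#' @return `path`, invisibly.
#' @export
write_encoded_atlas <- function(enc, path) {
  trees <- lapply(enc$forest, function(tr)
    list(dim = tr$dim, threshold = tr$threshold, left = tr$left,
         right = tr$right, dist = tr$dist))
  obj <- list(format = "froimal-encoder", version = 1L,
              source_subject_id = enc$source_subject_id,
              classes = enc$classes,
              n_samples = enc$n_samples,
              params = list(n_trees = enc$params$n_trees,
                            max_depth = enc$params$max_depth,
                            seed = enc$params$seed),
              trees = trees)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an encoded atlas written by [write_encoded_atlas()]
#'
#' @param path path to the serialized encoder.
#' @return An `encoded_atlas`.
#' @export
read_encoded_atlas <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "froimal-encoder") || obj$version != 1L)
    stop(sprintf("'%s' is not a version-1 froimal encoder file", path))
  K <- length(obj$classes)
  trees <- lapply(seq_len(nrow_or_len(obj$trees)), function(i) {
    tr <- tree_record(obj$trees, i)
    list(dim = as.integer(tr$dim),
         threshold = as.numeric(tr$threshold),
         left = as.integer(tr$left),
         right = as.integer(tr$right),
         dist = matrix(as.numeric(tr$dist), ncol = K))
  })
  structure(list(forest = trees, classes = as.integer(obj$classes),
                 params = forest_params(obj$params$n_trees,
                                        obj$params$max_depth,
                                        obj$params$seed),
                 source_subject_id = obj$source_subject_id,
                 n_samples = as.integer(obj$n_samples)),
            class = "encoded_atlas")
}

# jsonlite may simplify the tree list to a data.frame of list-columns
nrow_or_len <- function(x) if (is.data.frame(x)) nrow(x) else length(x)
tree_record <- function(x, i) {
  if (is.data.frame(x)) lapply(x, function(col) col[[i]]) else x[[i]]
}
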