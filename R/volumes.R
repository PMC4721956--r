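#' Activation map
#'
#' One subject's Z-statistic volume (e.g. the faces-versus-objects
#' localizer contrast) on the shared grid. Values must be finite
#' everywhere; NaN or Inf after load is an error, not silently masked.
#'
#' @param grid a [vol_grid()].
#' @param values numeric 3D array matching `grid$shape` (Z statistics).
#' @param subject_id subject identifier.
#' @return An `activation_map`.
#' @export
activation_map <- function(grid, values, subject_id) {
  values <- as.array(values)
  if (!identical(as.integer(dim(values)), grid$shape))
    stop("activation array does not match the grid shape")
  if (any(!is.finite(values)))
    stop(sprintf("activation map '%s' contains non-finite values", subject_id))
  storage.mode(values) <- "double"
  structure(list(grid = grid, values = values,
                 subject_id = as.character(subject_id)),
            class = "activation_map")
}

#' Label map
#'
#' Integer fROI labels per voxel; 0 is reserved for background. Every
#' nonzero label present in the volume must be named in `label_names`.
#'
#' @param grid a [vol_grid()].
#' @param labels integer 3D array matching `grid$shape`, values >= 0.
#' @param label_names named character vector mapping label id (as name)
#'   to region name, e.g. `c("1" = "rOFA", "2" = "rpFFA")`. Labels
#'   present in the array but unnamed are auto-named `"roi<k>"`.
#' @param subject_id optional subject identifier.
#' @return A `label_map`.
#' @export
label_map <- function(grid, labels, label_names = NULL, subject_id = "") {
  labels <- as.array(labels)
  if (!identical(as.integer(dim(labels)), grid$shape))
    stop("label array does not match the grid shape")
  if (any(!is.finite(labels)) || any(labels < 0) ||
      any(labels != round(labels)))
    stop("labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  present <- sort(setdiff(unique(as.vector(labels)), 0L))
  nm <- as.character(if (is.null(label_names)) character() else label_names)
  names(nm) <- names(label_names)
  for (l in present) {
    key <- as.character(l)
    if (is.null(names(nm)) || !(key %in% names(nm)))
      nm[key] <- paste0("roi", l)
  }
  structure(list(grid = grid, labels = labels, label_names = nm,
                 subject_id = as.character(subject_id)),
            class = "label_map")
}

#' Voxel set carrying a given label
#'
#' @param lm a [label_map()].
#' @param label integer label id.
#' @return Sorted integer vector of 1-based linear voxel indices.
#' @export
label_voxels <- function(lm, label) {
  which(as.vector(lm$labels) == as.integer(label))
}

#' Atlas: an activation map paired with its manual label map
#'
#' Construction enforces the atlas contract that every labeled voxel is
#' activated: labels sitting on voxels at or below `z_threshold` are
#' zeroed (manual delineations may graze the statistical threshold) and
#' the count of zeroed voxels is kept in `n_zeroed` and reported via
#' `message()`.
#'
#' @param activation an [activation_map()].
#' @param labels a [label_map()] on the same grid.
#' @param z_threshold activation threshold (default 2.3, i.e. p < 0.01
#'   uncorrected); comparisons are strict (`Z > z_threshold`).
#' @param quiet suppress the zeroed-voxel message.
#' @return An `atlas`.
#' @export
atlas <- function(activation, labels, z_threshold = 2.3, quiet = FALSE) {
  stopifnot(inherits(activation, "activation_map"), inherits(labels, "label_map"))
  stop_if_grid_mismatch(activation$grid, labels$grid, "activation and labels")
  if (nzchar(labels$subject_id) &&
      !identical(labels$subject_id, activation$subject_id))
    stop("subject ids of activation and label maps differ")
  bad <- labels$labels != 0L & !(activation$values > z_threshold)
  n_zeroed <- sum(bad)
  if (n_zeroed > 0) {
    labels$labels[bad] <- 0L
    if (!quiet)
      message(sprintf("atlas '%s': zeroed %d sub-threshold labeled voxel(s)",
                      activation$subject_id, n_zeroed))
  }
  labels$subject_id <- activation$subject_id
  structure(list(activation = activation, labels = labels,
                 subject_id = activation$subject_id,
                 z_threshold = z_threshold, n_zeroed = n_zeroed),
            class = "atlas")
}

#' Atlas database
#'
#' An ordered collection of atlases sharing one grid, with unique subject
#' ids.
#'
#' @param atlases list of [atlas()] objects.
#' @return An `atlas_db`.
#' @export
atlas_db <- function(atlases) {
  if (length(atlases) == 0) stop("empty atlas database")
  if (!all(vapply(atlases, inherits, logical(1), "atlas")))
    stop("all elements must be atlas objects")
  ids <- vapply(atlases, `[[`, character(1), "subject_id")
  if (anyDuplicated(ids)) stop("duplicate subject ids in atlas database")
  g <- atlases[[1]]$activation$grid
  for (a in atlases) stop_if_grid_mismatch(g, a$activation$grid, "atlases")
  names(atlases) <- ids
  structure(list(atlases = atlases, grid = g, subject_ids = ids),
            class = "atlas_db")
}

#' @export
print.atlas_db <- function(x, ...) {
  cat(sprintf("<atlas_db> %d atlases on %d x %d x %d grid\n",
              length(x$atlases), x$grid$shape[1], x$grid$shape[2],
              x$grid$shape[3]))
  invisible(x)
}

#' @export
length.atlas_db <- function(x) length(x$atlases)

#' Collective mask over a set of fROI labels
#'
#' The union, across every atlas in the database, of the voxels carrying
#' any of the requested labels. It provides the spatial constraint within
#' which candidate voxels are taken for training, prediction and
#' similarity ranking.
#'
#' @param db an [atlas_db()].
#' @param labels integer vector of fROI label ids to merge (nonempty).
#' @return A `collective_mask` with fields `grid`, `mask` (logical array)
#'   and `source_labels`.
#' @export
build_collective_mask <- function(db, labels) {
  stopifnot(inherits(db, "atlas_db"))
  labels <- sort(unique(as.integer(labels)))
  if (length(labels) == 0) stop("'labels' must be nonempty")
  if (any(labels <= 0)) stop("label ids must be positive (0 is background)")
  present <- sort(unique(unlist(lapply(db$atlases, function(a)
    setdiff(unique(as.vector(a$labels$labels)), 0L)))))
  unknown <- setdiff(labels, present)
  if (length(unknown) > 0)
    stop(sprintf("label id(s) %s not present in any atlas",
                 paste(unknown, collapse = ", ")))
  m <- array(FALSE, db$grid$shape)
  for (a in db$atlases)
    m <- m | (a$labels$labels %in% labels)
  dim(m) <- db$grid$shape
  if (!any(m))
    warning("collective mask is empty: no atlas carries the requested labels")
  structure(list(grid = db$grid, mask = m, source_labels = labels),
            class = "collective_mask")
}

#' Candidate voxels of a target map
#'
#' The sample set of the labeling problem: voxels strictly above the
#' activation threshold (`Z > z_threshold`; a voxel exactly at the
#' threshold is excluded) that also fall inside the collective mask,
#' returned in lexicographic (x, y, z) voxel-coordinate order.
#'
#' @param a an [activation_map()].
#' @param m a `collective_mask` on the same grid.
#' @param z_threshold activation threshold (default 2.3).
#' @return Integer vector of 1-based linear voxel indices.
#' @export
candidate_voxels <- function(a, m, z_threshold = 2.3) {
  stopifnot(inherits(a, "activation_map"), inherits(m, "collective_mask"))
  stop_if_grid_mismatch(a$grid, m$grid, "activation map and mask")
  idx <- which(as.vector(a$values > z_threshold) & as.vector(m$mask))
  order_lexicographic(a$grid, idx)
}

#' Per-voxel probabilistic label map
#'
#' Stores, for the evaluated voxel domain, a probability vector over an
#' ordered class list that always starts with background (0). Voxels
#' outside the domain implicitly carry the degenerate background vector.
#'
#' @param grid a [vol_grid()].
#' @param classes integer vector of class ids, first element 0.
#' @param voxels integer vector of evaluated (candidate) voxel indices.
#' @param probs numeric matrix `length(voxels) x length(classes)`; rows
#'   must be non-negative and sum to 1 (tolerance 1e-9).
#' @param subject_id optional subject identifier.
#' @return A `prob_label_map`.
#' @export
prob_label_map <- function(grid, classes, voxels, probs, subject_id = "") {
  classes <- as.integer(classes)
  if (length(classes) == 0 || classes[1] != 0L)
    stop("'classes' must start with background label 0")
  voxels <- as.integer(voxels)
  probs <- matrix(as.numeric(probs), nrow = length(voxels),
                  ncol = length(classes))
  if (length(voxels) > 0) {
    if (any(probs < -1e-12)) stop("negative probabilities")
    s <- rowSums(probs)
    if (any(abs(s - 1) > 1e-9))
      stop("per-voxel probabilities must sum to 1")
  }
  structure(list(grid = grid, classes = classes, voxels = voxels,
                 probs = probs, subject_id = as.character(subject_id)),
            class = "prob_label_map")
}

#' Expand a probabilistic label map to a dense 4D array
#'
#' @param p a [prob_label_map()].
#' @return Numeric 4D array (x, y, z, class); out-of-domain voxels have
#'   background probability 1.
#' @export
prob_map_array <- function(p) {
  K <- length(p$classes)
  out <- array(0, c(p$grid$shape, K))
  out[, , , 1] <- 1
  nvox <- prod(p$grid$shape)
  for (k in seq_len(K)) {
    plane <- array(if (k == 1) 1 else 0, p$grid$shape)
    plane[p$voxels] <- p$probs[, k]
    out[, , , k] <- plane
  }
  out
}
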