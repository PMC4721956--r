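# NIfTI-1 plumbing. Volumes are exchanged as .nii/.nii.gz through RNifti;
# label volumes are written as int16 with a JSON sidecar carrying label
# names and provenance (config hash + seed).

grid_from_nifti <- function(img, id) {
  aff <- RNifti::xform(img)
  vol_grid(dim(img)[1:3], matrix(as.numeric(aff), 4, 4), id = id)
}

nifti_with_grid <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  sp <- sqrt(colSums(grid$affine[1:3, 1:3]^2))
  RNifti::pixdim(img) <- c(sp, rep(1, length(dim(arr)) - 3L))
  RNifti::sform(img) <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- structure(grid$affine, code = 2L)
  img
}

#' Read an activation map from a NIfTI file
#'
#' @param path path to a `.nii`/`.nii.gz` Z-statistic volume.
#' @param subject_id subject identifier; default is the file stem.
#' @param grid optional [vol_grid()] the volume must match exactly.
#' @return An [activation_map()].
#' @export
read_activation_map <- function(path, subject_id = NULL, grid = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  g <- grid_from_nifti(img, id = basename(path))
  if (!is.null(grid)) {
    stop_if_grid_mismatch(grid, g, sprintf("'%s' and the experiment grid", path))
    g <- grid
  }
  vals <- array(as.vector(img, mode = "double"), g$shape)
  activation_map(g, vals, subject_id)
}

#' Write an activation map to NIfTI
#'
#' @param a an [activation_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_activation_map <- function(a, path) {
  RNifti::writeNifti(nifti_with_grid(a$values, a$grid), path,
                     datatype = "float")
  invisible(path)
}

#' Read a label map from NIfTI (+ optional JSON sidecar)
#'
#' A sidecar `<stem>.json` next to the volume, when present, supplies
#' `label_names` as an object mapping label id to region name.
#'
#' @param path path to an integer `.nii`/`.nii.gz` volume.
#' @param subject_id subject identifier; default is the file stem.
#' @param grid optional [vol_grid()] the volume must match exactly.
#' @return A [label_map()].
#' @export
read_label_map <- function(path, subject_id = NULL, grid = NULL) {
  img <- RNifti::readNifti(path)
  if (is.null(subject_id))
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  g <- grid_from_nifti(img, id = basename(path))
  if (!is.null(grid)) {
    stop_if_grid_mismatch(grid, g, sprintf("'%s' and the experiment grid", path))
    g <- grid
  }
  vals <- as.vector(img, mode = "double")
  if (any(abs(vals - round(vals)) > 1e-6))
    stop(sprintf("'%s' is not an integer label volume", path))
  vals <- array(as.integer(round(vals)), g$shape)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  nm <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(meta$label_names)) nm <- unlist(meta$label_names)
  }
  label_map(g, vals, label_names = nm, subject_id = subject_id)
}

#' Write a label map to NIfTI with a JSON sidecar
#'
#' @param lm a [label_map()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @param provenance optional named list merged into the sidecar (the
#'   pipeline stores the resolved config hash and seed here).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(lm, path, provenance = NULL) {
  RNifti::writeNifti(nifti_with_grid(lm$labels, lm$grid), path,
                     datatype = "int16")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  meta <- c(list(subject_id = lm$subject_id,
                 label_names = as.list(lm$label_names)),
            provenance)
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write fused class probabilities as a 4D NIfTI volume
#'
#' @param p a [prob_label_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prob_map <- function(p, path) {
  RNifti::writeNifti(nifti_with_grid(prob_map_array(p), p$grid), path,
                     datatype = "float")
  invisible(path)
}
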