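#' Volume grid
#'
#' A `vol_grid` describes the common stereotaxic sampling grid that every
#' volume in an experiment lives on: the array dimensions and the 4x4
#' voxel-to-world affine (mm). All activation maps, label maps and masks
#' that interact must share a bitwise-identical grid; this is checked at
#' every operation rather than silently resampled, because the package
#' deliberately performs no registration.
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world
#'   coordinates in mm. Defaults to 2 mm isotropic spacing at the origin.
#' @param id short text identifier for the grid (used in messages).
#' @return An object of class `vol_grid`.
#' @export
#' @examples
#' g <- vol_grid(c(32, 38, 28))
#' dim_prod <- prod(g$shape)
vol_grid <- function(shape, affine = NULL, id = "grid") {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("'shape' must be three integers >= 1")
  if (is.null(affine)) {
    affine <- diag(c(2, 2, 2, 1))
  }
  affine <- matrix(as.numeric(affine), 4, 4)
  if (any(!is.finite(affine)))
    stop("'affine' must be a finite 4x4 matrix")
  structure(list(shape = shape, affine = affine, id = as.character(id)),
            class = "vol_grid")
}

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf("<vol_grid '%s'> %d x %d x %d voxels, spacing %s mm\n",
              x$id, x$shape[1], x$shape[2], x$shape[3],
              paste(signif(sqrt(colSums(x$affine[1:3, 1:3]^2)), 3),
                    collapse = " x ")))
  invisible(x)
}

#' Test two grids for exact equality
#'
#' Grids are compatible only when shape and affine are bitwise equal.
#'
#' @param a,b `vol_grid` objects.
#' @return Logical scalar.
#' @export
same_grid <- function(a, b) {
  identical(a$shape, b$shape) && identical(a$affine, b$affine)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!same_grid(a, b))
    stop(sprintf("grid mismatch between %s: %s vs %s", what, a$id, b$id))
  invisible(TRUE)
}

#' Convert linear voxel indices to 0-based voxel coordinates
#'
#' Linear indices follow R's column-major array convention (1-based);
#' coordinates are 0-based integer (x, y, z) triples, the feature space of
#' the atlas encoders.
#'
#' @param grid a `vol_grid`.
#' @param idx integer vector of 1-based linear indices.
#' @return Integer matrix with columns x, y, z (0-based).
#' @export
voxel_coords <- function(grid, idx) {
  idx0 <- as.integer(idx) - 1L
  nx <- grid$shape[1]; ny <- grid$shape[2]
  x <- idx0 %% nx
  y <- (idx0 %/% nx) %% ny
  z <- idx0 %/% (nx * ny)
  cbind(x = x, y = y, z = z)
}

#' Convert 0-based voxel coordinates to linear indices
#'
#' @param grid a `vol_grid`.
#' @param coords integer matrix with columns x, y, z (0-based).
#' @return Integer vector of 1-based linear indices.
#' @export
voxel_index <- function(grid, coords) {
  coords <- matrix(as.integer(coords), ncol = 3)
  nx <- grid$shape[1]; ny <- grid$shape[2]
  as.integer(coords[, 1] + nx * (coords[, 2] + ny * coords[, 3]) + 1L)
}

#' Voxel coordinates in world (mm) space
#'
#' @param grid a `vol_grid`.
#' @param coords 0-based voxel coordinate matrix (columns x, y, z).
#' @return Numeric matrix of world coordinates in mm.
#' @export
voxel_to_mm <- function(grid, coords) {
  coords <- matrix(as.numeric(coords), ncol = 3)
  h <- cbind(coords, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

# order voxel linear indices lexicographically by (x, y, z)
order_lexicographic <- function(grid, idx) {
  cc <- voxel_coords(grid, idx)
  idx[order(cc[, 1], cc[, 2], cc[, 3])]
}
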