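# Atlas selection: rank reference atlases by similarity of the positive
# activation pattern to the target, within the collective mask.

masked_clamped <- function(a, mask) {
  v <- as.vector(a$values)[as.vector(mask$mask)]
  pmax(v, 0)
}

#' Positive-pattern Pearson similarity of two activation maps
#'
#' Both maps are restricted to the collective mask and negative Z values
#' are clamped to zero (fROIs are defined by positive contrast, so only
#' the positive pattern is informative); the similarity is the Pearson
#' correlation of the two clamped vectors. A constant clamped vector has
#' no informative pattern: the similarity is defined as 0, with a
#' warning.
#'
#' @param target,atlas_act [activation_map()] objects on the mask grid.
#' @param mask a `collective_mask` with at least 2 voxels.
#' @return Correlation in \[-1, 1\].
#' @export
activation_pattern_similarity <- function(target, atlas_act, mask) {
  stop_if_grid_mismatch(target$grid, mask$grid, "target and mask")
  stop_if_grid_mismatch(atlas_act$grid, mask$grid, "atlas and mask")
  if (sum(mask$mask) < 2) stop("mask must contain at least 2 voxels")
  x <- masked_clamped(target, mask)
  y <- masked_clamped(atlas_act, mask)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant clamped activation vector; similarity set to 0")
    return(0)
  }
  cor(x, y)
}

#' Normalized mutual information of two activation maps
#'
#' Masked (and by default clamped) Z vectors are discretized into
#' `n_bins` equal-width bins spanning the pooled value range, and the
#' similarity is `2 I(X;Y) / (H(X) + H(Y))` computed from the joint
#' histogram. Degenerate input occupying a single bin yields 0 with a
#' warning.
#'
#' @param target,atlas_act [activation_map()] objects on the mask grid.
#' @param mask a `collective_mask`.
#' @param n_bins number of histogram bins (>= 2, default 32).
#' @param clamp clamp negatives to zero first (default TRUE, matching the
#'   Pearson metric's positive-pattern reading).
#' @return NMI in \[0, 1\] (0 for independent, 1 for identical patterns).
#' @export
nmi_similarity <- function(target, atlas_act, mask, n_bins = 32L,
                           clamp = TRUE) {
  stop_if_grid_mismatch(target$grid, mask$grid, "target and mask")
  stop_if_grid_mismatch(atlas_act$grid, mask$grid, "atlas and mask")
  if (sum(mask$mask) < 2) stop("mask must contain at least 2 voxels")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("'n_bins' must be >= 2")
  x <- as.vector(target$values)[as.vector(mask$mask)]
  y <- as.vector(atlas_act$values)[as.vector(mask$mask)]
  if (clamp) { x <- pmax(x, 0); y <- pmax(y, 0) }
  rng <- range(c(x, y))
  if (diff(rng) == 0) {
    warning("degenerate (single-bin) input; NMI set to 0")
    return(0)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bx <- findInterval(x, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  by <- findInterval(y, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  joint <- table(factor(bx, levels = seq_len(n_bins)),
                 factor(by, levels = seq_len(n_bins)))
  nmi_from_joint(joint)
}

# NMI from a joint count table: 2 I(X;Y) / (H(X)+H(Y)), natural log
nmi_from_joint <- function(joint) {
  n <- sum(joint)
  pxy <- joint / n
  px <- rowSums(pxy); py <- colSums(pxy)
  hx <- -sum(px[px > 0] * log(px[px > 0]))
  hy <- -sum(py[py > 0] * log(py[py > 0]))
  if (hx + hy == 0) {
    warning("degenerate (single-bin) input; NMI set to 0")
    return(0)
  }
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  2 * mi / (hx + hy)
}

#' Rank reference atlases by similarity to a target
#'
#' Computes the chosen similarity between the target and every atlas in
#' the database and sorts descending; ties are broken by subject id
#' (lexicographic) so rankings are deterministic. As a leakage guard, a
#' target whose subject id is present in the database is rejected -
#' leave-one-subject-out bookkeeping is the caller's duty.
#'
#' @param target an [activation_map()] for the unlabeled subject.
#' @param db an [atlas_db()] (must not contain the target).
#' @param mask the experiment's `collective_mask`.
#' @param cfg an [experiment_config()]; `similarity_metric` selects
#'   Pearson or NMI.
#' @return A data.frame with columns `subject_id`, `similarity`, `rank`.
#' @export
rank_atlases <- function(target, db, mask, cfg = experiment_config()) {
  stopifnot(inherits(db, "atlas_db"))
  if (target$subject_id %in% db$subject_ids)
    stop(sprintf("target subject '%s' is present in the database (leakage)",
                 target$subject_id))
  sims <- vapply(db$atlases, function(a) {
    if (cfg$similarity_metric == "nmi")
      nmi_similarity(target, a$activation, mask, cfg$nmi_bins, cfg$nmi_clamp)
    else
      activation_pattern_similarity(target, a$activation, mask)
  }, numeric(1))
  ord <- order(-sims, db$subject_ids)
  data.frame(subject_id = db$subject_ids[ord],
             similarity = unname(sims[ord]),
             rank = seq_along(ord),
             stringsAsFactors = FALSE)
}

#' Select the top-N atlases from a ranking
#'
#' @param ranked a ranking from [rank_atlases()].
#' @param n number of atlases to keep; 0 means all (whole-database
#'   convention of [experiment_config()]).
#' @return Character vector of selected subject ids, best first.
#' @export
select_atlases <- function(ranked, n) {
  n <- as.integer(n)
  if (is.na(n) || n < 0L) stop("'n' must be >= 0")
  if (n > nrow(ranked))
    stop(sprintf("cannot select %d atlases from a ranking of %d", n,
                 nrow(ranked)))
  if (n == 0L) n <- nrow(ranked)
  ranked$subject_id[seq_len(n)]
}

#' Write a ranking to CSV
#'
#' @param ranked a ranking from [rank_atlases()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_ranking_csv <- function(ranked, path) {
  write.csv(ranked, path, row.names = FALSE)
  invisible(path)
}
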