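#' Forest hyperparameters
#'
#' @param n_trees number of trees T (default 30).
#' @param max_depth depth cap D (default 20).
#' @param seed master seed; tree t uses the derived stream `seed + t - 1`.
#' @return A `forest_params` object.
#' @export
forest_params <- function(n_trees = 30L, max_depth = 20L, seed = 1L) {
  n_trees <- as.integer(n_trees); max_depth <- as.integer(max_depth)
  seed <- as.integer(seed)
  if (is.na(n_trees) || n_trees < 1L) stop("'n_trees' must be >= 1")
  if (is.na(max_depth) || max_depth < 1L) stop("'max_depth' must be >= 1")
  if (is.na(seed)) stop("'seed' must be an integer")
  structure(list(n_trees = n_trees, max_depth = max_depth, seed = seed),
            class = "forest_params")
}

#' Experiment configuration
#'
#' Collects every tunable of the labeling pipeline at the operating point
#' used throughout: activation threshold Z > 2.3, top-40 atlas selection,
#' forests of 30 trees grown to depth 20, and maximum-probability-map
#' thresholds 0, 0.1 and 0.2 for the single-atlas baseline.
#'
#' @param z_threshold activation threshold (strict), default 2.3.
#' @param n_selected_atlases number of top-ranked atlases N fused per
#'   target; 0 means use the whole database. Default 40.
#' @param mpm_thresholds probability thresholds for the GSS baseline's
#'   maximum probability map, sorted, each in \[0, 1\].
#' @param forest a [forest_params()].
#' @param similarity_metric `"pearson"` (positive-pattern correlation) or
#'   `"nmi"` (normalized mutual information).
#' @param peak_match_radius_mm tolerance radius for peak-consistency
#'   matching; 0 requires the identical voxel.
#' @param nmi_bins number of equal-width bins for the NMI metric.
#' @param nmi_clamp clamp negative Z to zero before binning for NMI (the
#'   Pearson metric always clamps).
#' @param vote `"soft"` averages each leaf's class distribution across
#'   trees; `"hard"` gives each tree one vote for its leaf's modal class.
#' @return An `experiment_config` object.
#' @export
experiment_config <- function(z_threshold = 2.3,
                              n_selected_atlases = 40L,
                              mpm_thresholds = c(0, 0.1, 0.2),
                              forest = forest_params(),
                              similarity_metric = c("pearson", "nmi"),
                              peak_match_radius_mm = 0,
                              nmi_bins = 32L,
                              nmi_clamp = TRUE,
                              vote = c("soft", "hard")) {
  similarity_metric <- match.arg(similarity_metric)
  vote <- match.arg(vote)
  if (!is.numeric(z_threshold) || z_threshold <= 0)
    stop("'z_threshold' must be > 0")
  n_selected_atlases <- as.integer(n_selected_atlases)
  if (is.na(n_selected_atlases) || n_selected_atlases < 0L)
    stop("'n_selected_atlases' must be >= 0 (0 = use all)")
  mpm_thresholds <- as.numeric(mpm_thresholds)
  if (any(mpm_thresholds < 0) || any(mpm_thresholds > 1) ||
      is.unsorted(mpm_thresholds))
    stop("'mpm_thresholds' must be sorted values in [0, 1]")
  stopifnot(inherits(forest, "forest_params"))
  if (peak_match_radius_mm < 0) stop("'peak_match_radius_mm' must be >= 0")
  nmi_bins <- as.integer(nmi_bins)
  if (is.na(nmi_bins) || nmi_bins < 2L) stop("'nmi_bins' must be >= 2")
  structure(list(z_threshold = z_threshold,
                 n_selected_atlases = n_selected_atlases,
                 mpm_thresholds = mpm_thresholds,
                 forest = forest,
                 similarity_metric = similarity_metric,
                 peak_match_radius_mm = peak_match_radius_mm,
                 nmi_bins = nmi_bins,
                 nmi_clamp = isTRUE(nmi_clamp),
                 vote = vote),
            class = "experiment_config")
}

# stable short hash of a resolved config, embedded in output sidecars so
# artifacts can be traced to the run that produced them (rolling
# polynomial hash; no cryptographic intent)
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

config_to_list <- function(cfg) {
  list(z_threshold = cfg$z_threshold,
       n_selected_atlases = cfg$n_selected_atlases,
       mpm_thresholds = cfg$mpm_thresholds,
       forest = list(n_trees = cfg$forest$n_trees,
                     max_depth = cfg$forest$max_depth,
                     seed = cfg$forest$seed),
       similarity_metric = cfg$similarity_metric,
       peak_match_radius_mm = cfg$peak_match_radius_mm,
       nmi_bins = cfg$nmi_bins,
       nmi_clamp = cfg$nmi_clamp,
       vote = cfg$vote)
}

config_from_list <- function(x) {
  base <- config_to_list(experiment_config())
  x <- modifyList(base, x[intersect(names(x), names(base))])
  experiment_config(z_threshold = x$z_threshold,
                    n_selected_atlases = x$n_selected_atlases,
                    mpm_thresholds = unlist(x$mpm_thresholds),
                    forest = forest_params(x$forest$n_trees,
                                           x$forest$max_depth,
                                           x$forest$seed),
                    similarity_metric = x$similarity_metric,
                    peak_match_radius_mm = x$peak_match_radius_mm,
                    nmi_bins = x$nmi_bins,
                    nmi_clamp = x$nmi_clamp,
                    vote = x$vote)
}
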