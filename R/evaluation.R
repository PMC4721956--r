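# Metrics and experiment drivers: Dice overlap, peak-location
# consistency, leave-one-subject-out cross-validation (LOSOCV) over the
# labeling methods, the atlas-count sweep, the forest-parameter grid,
# and intensity concordance with Steiger's Z test.

#' Dice coefficient of two voxel sets
#'
#' `2|A n B| / (|A| + |B|)`. When both sets are empty the overlap is
#' undefined and `NA` is returned (such cases are excluded from
#' averages, not counted as 0 or 1); when exactly one is empty the Dice
#' is 0.
#'
#' @param a,b integer vectors of linear voxel indices on one grid.
#' @return Dice in \[0, 1\], or `NA` if both sets are empty.
#' @export
dice_coefficient <- function(a, b) {
  a <- unique(as.integer(a)); b <- unique(as.integer(b))
  if (length(a) == 0 && length(b) == 0) return(NA_real_)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Peak-location consistency of an automatic region
#'
#' TRUE iff the maximal-Z voxel of the automatically labeled region lies
#' within `radius_mm` of the maximal-Z voxel of the manual region
#' (radius 0 requires the identical voxel). FALSE if the automatic
#' region is empty; undefined (`NA`) if the manual region is empty.
#' Argmax ties are broken by lexicographic voxel order.
#'
#' @param auto,manual [label_map()] objects on one grid.
#' @param act the subject's [activation_map()].
#' @param label fROI label id to examine.
#' @param radius_mm match tolerance in mm (default 0: exact voxel).
#' @return Logical scalar or `NA`.
#' @export
peak_consistency <- function(auto, manual, act, label, radius_mm = 0) {
  stop_if_grid_mismatch(auto$grid, manual$grid, "auto and manual labels")
  stop_if_grid_mismatch(auto$grid, act$grid, "labels and activation")
  mvox <- label_voxels(manual, label)
  if (length(mvox) == 0) return(NA)
  avox <- label_voxels(auto, label)
  if (length(avox) == 0) return(FALSE)
  pk <- function(vox) {
    vox <- order_lexicographic(act$grid, vox)
    vox[which.max(as.vector(act$values)[vox])]
  }
  pa <- pk(avox); pm <- pk(mvox)
  if (pa == pm) return(TRUE)
  if (radius_mm <= 0) return(FALSE)
  d <- voxel_to_mm(act$grid, voxel_coords(act$grid, pa)) -
       voxel_to_mm(act$grid, voxel_coords(act$grid, pm))
  sqrt(sum(d^2)) <= radius_mm
}

#' Mean activation intensity within a labeled region
#'
#' @param act an [activation_map()].
#' @param lm a [label_map()].
#' @param label fROI label id.
#' @return Mean Z over the region's voxels, or `NA` if the region is
#'   empty.
#' @export
mean_region_z <- function(act, lm, label) {
  stop_if_grid_mismatch(act$grid, lm$grid, "activation and labels")
  vox <- label_voxels(lm, label)
  if (length(vox) == 0) return(NA_real_)
  mean(as.vector(act$values)[vox])
}

#' Precompute the shared state of a LOSOCV experiment
#'
#' Builds, once: the collective mask, each subject's candidate voxel
#' set, each atlas's encoder (an encoder depends only on its own atlas,
#' never on the fold), the full pairwise similarity matrix, and every
#' (target, atlas) per-voxel forest prediction. All LOSOCV drivers
#' ([losocv()], [atlas_count_sweep()], [atlas_rank_accuracy()]) accept
#' this object so repeated analyses of one cohort do not retrain or
#' re-predict.
#'
#' @param db an [atlas_db()].
#' @param labels integer vector of fROI label ids.
#' @param cfg an [experiment_config()].
#' @param predictions also cache per-pair forest predictions (default
#'   TRUE; disable to save memory when only similarities are needed).
#' @return A `mal_precompute` list.
#' @export
mal_precompute <- function(db, labels, cfg = experiment_config(),
                           predictions = TRUE) {
  stopifnot(inherits(db, "atlas_db"))
  labels <- sort(unique(as.integer(labels)))
  classes <- c(0L, labels)
  mask <- build_collective_mask(db, labels)
  ids <- db$subject_ids
  n <- length(ids)
  cand <- lapply(db$atlases, function(a)
    candidate_voxels(a$activation, mask, cfg$z_threshold))
  encoders <- lapply(db$atlases, function(a)
    train_atlas_encoder(a, mask, labels, cfg))
  sim <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (j < i) { sim[i, j] <- sim[j, i]; next }   # metrics are symmetric
    sim[i, j] <- if (cfg$similarity_metric == "nmi")
      nmi_similarity(db$atlases[[i]]$activation, db$atlases[[j]]$activation,
                     mask, cfg$nmi_bins, cfg$nmi_clamp)
    else
      activation_pattern_similarity(db$atlases[[i]]$activation,
                                    db$atlases[[j]]$activation, mask)
  }
  pred <- NULL
  if (predictions) {
    pred <- lapply(seq_len(n), function(i) {
      X <- voxel_coords(db$grid, cand[[i]])
      p <- lapply(seq_len(n), function(j) {
        if (i == j) return(NULL)
        enc <- encoders[[j]]
        raw <- .df_predict(enc$forest, X, length(enc$classes),
                           cfg$vote == "hard")
        out <- matrix(0, nrow(raw), length(classes))
        out[, match(enc$classes, classes)] <- raw
        out
      })
      names(p) <- ids
      p
    })
    names(pred) <- ids
  }
  structure(list(db = db, labels = labels, classes = classes, mask = mask,
                 cand = cand, encoders = encoders, sim = sim, pred = pred,
                 cfg = cfg),
            class = "mal_precompute")
}

# ranking of references for target id, from the cached similarity matrix
# (descending similarity, ties by subject id - same rule as rank_atlases)
ranked_ids <- function(prep, target_id, reference_ids) {
  s <- prep$sim[target_id, reference_ids]
  reference_ids[order(-s, reference_ids)]
}

# fuse the cached predictions of the given atlases for one target and
# return the voted labels at the target's candidate voxels; summation in
# canonical subject order so fusion is exactly permutation-invariant
fused_vote <- function(prep, target_id, atlas_ids) {
  acc <- Reduce(`+`, prep$pred[[target_id]][sort(atlas_ids)])
  win <- max.col(acc, ties.method = "first")  # classes bg-first, ascending
  prep$classes[win]
}

# image-based transfer votes at the target's candidate voxels
transfer_vote <- function(prep, target_id, atlas_ids) {
  vox <- prep$cand[[target_id]]
  K <- length(prep$classes)
  acc <- matrix(0, length(vox), K)
  for (id in sort(atlas_ids)) {
    lab <- as.vector(prep$db$atlases[[id]]$labels$labels)[vox]
    lab[!(lab %in% prep$labels)] <- 0L
    acc[cbind(seq_along(vox), match(lab, prep$classes))] <-
      acc[cbind(seq_along(vox), match(lab, prep$classes))] + 1
  }
  prep$classes[max.col(acc, ties.method = "first")]
}

label_map_from_votes <- function(prep, target_id, votes) {
  lab <- array(0L, prep$db$grid$shape)
  lab[prep$cand[[target_id]]] <- votes
  label_map(prep$db$grid, lab, subject_id = target_id)
}

score_fold <- function(prep, target_id, auto, method, n_atlases) {
  a <- prep$db$atlases[[target_id]]
  rows <- lapply(prep$labels, function(l) {
    d <- dice_coefficient(label_voxels(auto, l),
                          label_voxels(a$labels, l))
    pm <- peak_consistency(auto, a$labels, a$activation, l,
                           prep$cfg$peak_match_radius_mm)
    data.frame(target_subject = target_id, method = method,
               roi_label = l, dice = d,
               peak_match = as.numeric(pm),
               n_atlases = n_atlases,
               n_trees = prep$cfg$forest$n_trees,
               max_depth = prep$cfg$forest$max_depth,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Leave-one-subject-out cross-validation of the labeling methods
#'
#' Each subject is iteratively held out and labeled from the remaining
#' atlases by every requested method; the result is scored against the
#' held-out subject's manual labels (Dice per fROI, peak-location
#' match). Methods: `"mal"` (forest encoding + atlas selection +
#' fusion), `"image_based"` (direct label transfer over all remaining
#' atlases), `"gss"` and `"gss_as"` (single-atlas baseline without/with
#' atlas selection; their Dice and peak columns are means across the
#' configured MPM thresholds).
#'
#' @param db an [atlas_db()] with >= 2 atlases.
#' @param labels integer vector of fROI label ids.
#' @param cfg an [experiment_config()].
#' @param methods subset of `c("mal", "image_based", "gss", "gss_as")`.
#' @param prep optional [mal_precompute()] of the same cohort/config.
#' @return Data.frame of evaluation records: `target_subject`, `method`,
#'   `roi_label`, `dice`, `peak_match`, `n_atlases`, `n_trees`,
#'   `max_depth`.
#' @export
losocv <- function(db, labels, cfg = experiment_config(),
                   methods = "mal", prep = NULL) {
  stopifnot(inherits(db, "atlas_db"))
  if (length(db$atlases) < 2) stop("LOSOCV needs at least 2 atlases")
  methods <- match.arg(methods, c("mal", "image_based", "gss", "gss_as"),
                       several.ok = TRUE)
  if (is.null(prep))
    prep <- mal_precompute(db, labels, cfg,
                           predictions = "mal" %in% methods)
  ids <- db$subject_ids
  n_sel <- cfg$n_selected_atlases
  if (n_sel > length(ids) - 1)
    stop(sprintf("n_selected_atlases (%d) exceeds the fold size (%d)",
                 n_sel, length(ids) - 1))
  # per-label indicator sums over all atlases, for fast per-fold GSS maps
  need_gss <- any(c("gss", "gss_as") %in% methods)
  if (need_gss) {
    ind_sum <- lapply(prep$labels, function(l)
      Reduce(`+`, lapply(db$atlases, function(a)
        array(as.numeric(a$labels$labels == l), db$grid$shape))))
    names(ind_sum) <- as.character(prep$labels)
  }
  out <- list()
  for (tid in ids) {
    refs <- setdiff(ids, tid)
    stopifnot(!(tid %in% refs))   # leakage guard, asserted every fold
    ranked <- ranked_ids(prep, tid, refs)
    if ("mal" %in% methods) {
      chosen <- if (n_sel == 0) ranked else ranked[seq_len(n_sel)]
      auto <- label_map_from_votes(prep, tid, fused_vote(prep, tid, chosen))
      out[[length(out) + 1]] <- score_fold(prep, tid, auto, "mal",
                                           length(chosen))
    }
    if ("image_based" %in% methods) {
      auto <- label_map_from_votes(prep, tid, transfer_vote(prep, tid, refs))
      out[[length(out) + 1]] <- score_fold(prep, tid, auto, "image_based",
                                           length(refs))
    }
    for (mth in intersect(c("gss", "gss_as"), methods)) {
      subset_ids <- if (mth == "gss_as") {
        if (n_sel == 0) ranked else ranked[seq_len(min(n_sel, length(ranked)))]
      } else refs
      rec <- gss_fold_record(prep, ind_sum, tid, subset_ids, mth)
      out[[length(out) + 1]] <- rec
    }
  }
  do.call(rbind, out)
}

# one GSS/GSS+AS fold: Dice and peak match averaged over MPM thresholds
gss_fold_record <- function(prep, ind_sum, target_id, subset_ids, method) {
  db <- prep$db; cfg <- prep$cfg
  a <- db$atlases[[target_id]]
  n_ref <- length(subset_ids)
  all_ids <- db$subject_ids
  full_subset <- setequal(subset_ids, setdiff(all_ids, target_id))
  pm <- lapply(prep$labels, function(l) {
    if (full_subset) {
      (ind_sum[[as.character(l)]] -
         (db$atlases[[target_id]]$labels$labels == l)) / n_ref
    } else {
      Reduce(`+`, lapply(db$atlases[subset_ids], function(x)
        array(as.numeric(x$labels$labels == l), db$grid$shape))) / n_ref
    }
  })
  names(pm) <- as.character(prep$labels)
  act_ok <- a$activation$values > cfg$z_threshold
  per_thr <- lapply(cfg$mpm_thresholds, function(thr) {
    mpm <- build_mpm(pm, thr, db$grid)
    lab <- mpm$labels
    lab[!act_ok] <- 0L
    auto <- label_map(db$grid, lab, subject_id = target_id)
    score_fold(prep, target_id, auto, method, n_ref)
  })
  rec <- per_thr[[1]]
  rec$dice <- rowMeans(do.call(cbind, lapply(per_thr, `[[`, "dice")),
                       na.rm = TRUE)
  rec$peak_match <- rowMeans(do.call(cbind, lapply(per_thr, `[[`, "peak_match")),
                             na.rm = TRUE)
  rec$dice[is.nan(rec$dice)] <- NA_real_
  rec$peak_match[is.nan(rec$peak_match)] <- NA_real_
  rec
}

#' Pairwise atlas similarity before and after forest encoding
#'
#' For a pair of atlases, the per-fROI Dice between the two raw label
#' maps (`dice_original`) and between the two hard label maps obtained
#' by applying each atlas's encoder over a common prediction domain
#' (`dice_encoded`). The default domain is the full collective mask;
#' `domain = "union"` instead predicts on the union of the two atlases'
#' candidate voxel sets.
#'
#' @param a1,a2 [atlas()] objects on the mask grid.
#' @param mask the experiment's `collective_mask`.
#' @param labels integer vector of fROI label ids.
#' @param cfg an [experiment_config()].
#' @param domain `"mask"` (default) or `"union"`.
#' @param enc1,enc2 optional precomputed encoders for `a1`, `a2`.
#' @return Data.frame with columns `roi_label`, `dice_original`,
#'   `dice_encoded`.
#' @export
pairwise_encoded_similarity <- function(a1, a2, mask, labels,
                                        cfg = experiment_config(),
                                        domain = c("mask", "union"),
                                        enc1 = NULL, enc2 = NULL) {
  domain <- match.arg(domain)
  labels <- sort(unique(as.integer(labels)))
  classes <- c(0L, labels)
  if (is.null(enc1)) enc1 <- train_atlas_encoder(a1, mask, labels, cfg)
  if (is.null(enc2)) enc2 <- train_atlas_encoder(a2, mask, labels, cfg)
  vox <- if (domain == "mask") which(as.vector(mask$mask)) else
    sort(union(candidate_voxels(a1$activation, mask, cfg$z_threshold),
               candidate_voxels(a2$activation, mask, cfg$z_threshold)))
  vox <- order_lexicographic(mask$grid, vox)
  X <- voxel_coords(mask$grid, vox)
  hard <- function(enc) {
    raw <- .df_predict(enc$forest, X, length(enc$classes),
                       cfg$vote == "hard")
    out <- matrix(0, nrow(raw), length(classes))
    out[, match(enc$classes, classes)] <- raw
    classes[max.col(out, ties.method = "first")]
  }
  h1 <- hard(enc1); h2 <- hard(enc2)
  rows <- lapply(labels, function(l) {
    data.frame(roi_label = l,
               dice_original = dice_coefficient(label_voxels(a1$labels, l),
                                                label_voxels(a2$labels, l)),
               dice_encoded = dice_coefficient(vox[h1 == l], vox[h2 == l]))
  })
  do.call(rbind, rows)
}

#' Per-atlas rank versus single-atlas labeling accuracy
#'
#' For every (target, reference) pair: the reference's similarity rank
#' for that target and the Dice (averaged over fROIs) obtained when the
#' reference's encoder alone labels the target. The Spearman correlation
#' of rank with accuracy, per target, quantifies whether
#' activation-pattern similarity predicts label-transfer quality.
#'
#' @param db an [atlas_db()].
#' @param labels integer vector of fROI label ids.
#' @param cfg an [experiment_config()].
#' @param prep optional [mal_precompute()] of the same cohort/config.
#' @return List with `pairs` (data.frame: `target_subject`, `atlas`,
#'   `rank`, `dice`) and `spearman_by_target` (named vector), and
#'   `mean_spearman`.
#' @export
atlas_rank_accuracy <- function(db, labels, cfg = experiment_config(),
                                prep = NULL) {
  if (is.null(prep)) prep <- mal_precompute(db, labels, cfg)
  ids <- db$subject_ids
  rows <- list()
  for (tid in ids) {
    refs <- ranked_ids(prep, tid, setdiff(ids, tid))
    manual <- prep$db$atlases[[tid]]$labels
    for (k in seq_along(refs)) {
      votes <- fused_vote(prep, tid, refs[k])
      auto <- label_map_from_votes(prep, tid, votes)
      d <- vapply(prep$labels, function(l)
        dice_coefficient(label_voxels(auto, l), label_voxels(manual, l)),
        numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        target_subject = tid, atlas = refs[k], rank = k,
        dice = mean(d, na.rm = TRUE), stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  sp <- vapply(split(pairs, pairs$target_subject), function(df) {
    if (sd(df$dice) == 0) return(NA_real_)
    cor(df$rank, df$dice, method = "spearman")
  }, numeric(1))
  list(pairs = pairs, spearman_by_target = sp,
       mean_spearman = mean(sp, na.rm = TRUE))
}

#' Atlas-count sweep: top-ranked versus random subsets
#'
#' For each subset size, the LOSOCV mean Dice over all targets and fROIs
#' when fusing (a) the top-ranked atlases and (b) `n_random_repeats`
#' random subsets of the same size (seeded; the mean over repeats is
#' reported).
#'
#' @param db an [atlas_db()].
#' @param labels integer vector of fROI label ids.
#' @param cfg an [experiment_config()].
#' @param counts integer vector of subset sizes (each <= db size - 1).
#' @param n_random_repeats random subsets per size (default 10).
#' @param seed seed for the random subsets (default the forest seed).
#' @param prep optional [mal_precompute()].
#' @return Data.frame with columns `n_atlases`, `dice_ranked`,
#'   `dice_random`.
#' @export
atlas_count_sweep <- function(db, labels, cfg = experiment_config(),
                              counts = c(1, 5, 10, 20, 40),
                              n_random_repeats = 10L, seed = NULL,
                              prep = NULL) {
  counts <- as.integer(counts)
  n <- length(db$atlases)
  if (any(counts < 1) || any(counts > n - 1))
    stop("each count must be between 1 and database size - 1")
  if (is.null(seed)) seed <- cfg$forest$seed
  if (is.null(prep)) prep <- mal_precompute(db, labels, cfg)
  ids <- db$subject_ids
  mean_dice_for <- function(choose_fun) {
    d <- unlist(lapply(ids, function(tid) {
      subset_ids <- choose_fun(tid)
      auto <- label_map_from_votes(prep, tid,
                                   fused_vote(prep, tid, subset_ids))
      manual <- prep$db$atlases[[tid]]$labels
      vapply(prep$labels, function(l)
        dice_coefficient(label_voxels(auto, l), label_voxels(manual, l)),
        numeric(1))
    }))
    mean(d, na.rm = TRUE)
  }
  rows <- lapply(counts, function(k) {
    ranked_mean <- mean_dice_for(function(tid)
      ranked_ids(prep, tid, setdiff(ids, tid))[seq_len(k)])
    rnd <- with_seed(seed + k, vapply(seq_len(n_random_repeats), function(r) {
      picks <- lapply(ids, function(tid) sample(setdiff(ids, tid), k))
      names(picks) <- ids
      mean_dice_for(function(tid) picks[[tid]])
    }, numeric(1)))
    data.frame(n_atlases = k, dice_ranked = ranked_mean,
               dice_random = mean(rnd))
  })
  do.call(rbind, rows)
}

#' Forest-parameter grid evaluation
#'
#' LOSOCV mean Dice of the multi-atlas method for every (T, D) pair;
#' used to assess the (in)sensitivity of the labeling to the forest
#' hyperparameters.
#'
#' @param db an [atlas_db()].
#' @param labels integer vector of fROI label ids.
#' @param cfg an [experiment_config()] (its forest seed is reused).
#' @param t_values,d_values integer vectors of tree counts and depth
#'   caps.
#' @return Matrix of mean Dice, rows = `t_values`, cols = `d_values`.
#' @export
forest_param_grid <- function(db, labels, cfg = experiment_config(),
                              t_values = seq(10, 40, by = 5),
                              d_values = seq(10, 40, by = 5)) {
  out <- matrix(NA_real_, length(t_values), length(d_values),
                dimnames = list(paste0("T", t_values), paste0("D", d_values)))
  for (i in seq_along(t_values)) for (j in seq_along(d_values)) {
    cfg_ij <- cfg
    cfg_ij$forest <- forest_params(t_values[i], d_values[j],
                                   cfg$forest$seed)
    rec <- losocv(db, labels, cfg_ij, methods = "mal")
    out[i, j] <- mean(rec$dice, na.rm = TRUE)
  }
  out
}

#' Steiger's Z for two dependent correlations sharing a variable
#'
#' Tests whether `cor(x, y1)` differs from `cor(x, y2)` when both
#' correlations share the common index `x` (one-common-index case, with
#' the pooled-estimate covariance correction and Fisher-transformed
#' correlations).
#'
#' @param r12 correlation of the common variable with the first measure.
#' @param r13 correlation of the common variable with the second.
#' @param r23 correlation between the two measures.
#' @param n sample size (>= 4).
#' @return List with `z` and two-sided `p`.
#' @export
steiger_z <- function(r12, r13, r23, n) {
  if (n < 4) stop("Steiger's Z needs n >= 4")
  rbar <- (r12 + r13) / 2
  det3 <- 1 + 2 * r12 * r13 * r23 - r12^2 - r13^2 - r23^2
  if (det3 < -1e-8) stop("inconsistent correlation triple")
  psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  sbar <- psi / (1 - rbar^2)^2
  z12 <- atanh(r12); z13 <- atanh(r13)
  if (identical(r12, r13)) return(list(z = 0, p = 1))
  z <- (z12 - z13) * sqrt(n - 3) / sqrt(2 - 2 * sbar)
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Concordance of automatic and manual region intensities
#'
#' Correlates per-subject mean activation intensities extracted from two
#' automatically identified versions of a region with those from the
#' manual delineation, and compares the two dependent correlations with
#' Steiger's Z. Subjects with an undefined mean (empty region, `NA`) in
#' any vector are excluded pairwise.
#'
#' @param manual_means,auto_means_1,auto_means_2 equal-length numeric
#'   vectors of per-subject mean Z.
#' @return List with `r1`, `r2`, `steiger_z`, `p`, `n`.
#' @export
intensity_concordance <- function(manual_means, auto_means_1, auto_means_2) {
  if (length(auto_means_1) != length(manual_means) ||
      length(auto_means_2) != length(manual_means))
    stop("input vectors must have equal length")
  keep <- is.finite(manual_means) & is.finite(auto_means_1) &
    is.finite(auto_means_2)
  m <- manual_means[keep]; a1 <- auto_means_1[keep]; a2 <- auto_means_2[keep]
  n <- length(m)
  if (n < 4) stop("need at least 4 complete observations")
  if (sd(m) == 0 || sd(a1) == 0 || sd(a2) == 0)
    stop("constant vectors have no defined correlation")
  r1 <- cor(m, a1); r2 <- cor(m, a2); r23 <- cor(a1, a2)
  st <- steiger_z(r1, r2, r23, n)
  list(r1 = r1, r2 = r2, steiger_z = st$z, p = st$p, n = n)
}
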