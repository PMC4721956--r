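gss_cohort <- function() cached_fixture("gss_cohort", function()
  generate_population(population_spec(n_subjects = 12, seed = 19)))

test_that("probabilistic maps are exact rationals k/n", {
  g <- vol_grid(c(6, 6, 4))
  mk <- function(id, vox) {
    z <- array(0, g$shape); z[vox] <- 5
    lab <- array(0L, g$shape); lab[vox] <- 1L
    atlas(activation_map(g, z, id), label_map(g, lab, subject_id = id),
          quiet = TRUE)
  }
  a2 <- list(mk("a", c(5L, 6L)), mk("b", c(5L, 9L)))
  pm <- build_probabilistic_maps(a2, 1L)
  expect_equal(pm[["1"]][5], 1.0)   # labeled in both
  expect_equal(pm[["1"]][6], 0.5)
  a4 <- list(mk("a", 5L), mk("b", 6L), mk("c", 7L), mk("d", 8L))
  pm4 <- build_probabilistic_maps(a4, 1L)
  expect_equal(pm4[["1"]][5], 0.25) # labeled in 1 of 4
  # every value is k/n for integer k
  pop <- gss_cohort()
  pmr <- build_probabilistic_maps(pop$db$atlases, c(1, 2))
  n <- length(pop$db$atlases)
  for (p in pmr)
    expect_true(all(abs(p * n - round(p * n)) < 1e-9))
  # mean-of-indicators oracle on random binary stacks
  sets <- lapply(1:5, function(i)
    with_seed_local(i + 200, sample(prod(g$shape), 20)))
  atl <- lapply(seq_along(sets), function(i) mk(paste0("r", i), sets[[i]]))
  pmo <- build_probabilistic_maps(atl, 1L)[["1"]]
  oracle <- Reduce(`+`, lapply(sets, function(s) {
    ind <- array(0, g$shape); ind[s] <- 1; ind
  })) / 5
  expect_equal(as.vector(pmo), as.vector(oracle), tolerance = 1e-12)
  expect_error(build_probabilistic_maps(list(), 1L), "empty")
})

test_that("MPM thresholds and argmax follow the documented rules", {
  g <- vol_grid(c(2, 2, 1))
  pm <- list("1" = array(c(0.4, 0.2, 0.0, 0.3), c(2, 2, 1)),
             "2" = array(c(0.3, 0.2, 0.0, 0.6), c(2, 2, 1)))
  m02 <- build_mpm(pm, 0.2, g)
  expect_identical(as.vector(m02$labels), c(1L, 1L, 0L, 2L))  # tie -> lowest id
  m05 <- build_mpm(pm, 0.5, g)
  expect_identical(as.vector(m05$labels), c(0L, 0L, 0L, 2L))
  # threshold 0 equals the plain voxelwise argmax oracle
  g2 <- vol_grid(c(8, 8, 4))
  pmr <- lapply(1:3, function(i)
    array(with_seed_local(i + 300, round(runif(prod(g2$shape)), 2)),
          g2$shape))
  names(pmr) <- c("1", "2", "3")
  m0 <- build_mpm(pmr, 0, g2)
  stack <- cbind(as.vector(pmr[[1]]), as.vector(pmr[[2]]),
                 as.vector(pmr[[3]]))
  oracle <- integer(nrow(stack))
  for (i in seq_len(nrow(stack))) {
    if (max(stack[i, ]) > 0) oracle[i] <- which.max(stack[i, ])
  }
  expect_identical(as.vector(m0$labels), oracle)
  # monotone shrinkage of the labeled set as the threshold rises
  lab_set <- function(thr) which(as.vector(build_mpm(pmr, thr, g2)$labels) != 0L)
  s0 <- lab_set(0); s1 <- lab_set(0.1); s2 <- lab_set(0.2)
  expect_true(all(s1 %in% s0))
  expect_true(all(s2 %in% s1))
})

test_that("GSS output is the MPM intersected with the supra-threshold set", {
  pop <- gss_cohort()
  cfg <- experiment_config(n_selected_atlases = 5L)
  tgt <- pop$db$atlases[[12]]
  refs <- pop$db$atlases[1:11]
  # no supra-threshold voxels -> all background
  flat <- activation_map(pop$db$grid, array(0, pop$db$grid$shape), "flat")
  out0 <- gss_label_subject(flat, refs, c(1, 2), cfg, threshold = 0)
  expect_true(all(out0$labels == 0L))
  # staged-composition oracle
  for (thr in c(0, 0.1, 0.2)) {
    got <- gss_label_subject(tgt$activation, refs, c(1, 2), cfg, thr)
    pm <- build_probabilistic_maps(refs, c(1, 2))
    mpm <- build_mpm(pm, thr, pop$db$grid)
    oracle <- mpm$labels
    oracle[!(tgt$activation$values > cfg$z_threshold)] <- 0L
    expect_identical(got$labels, oracle)
    # invariant: output within supra-threshold AND MPM-labeled voxels
    lab <- which(as.vector(got$labels) != 0L)
    expect_true(all(as.vector(tgt$activation$values)[lab] > cfg$z_threshold))
    expect_true(all(as.vector(mpm$labels)[lab] != 0L))
  }
  # leakage guard
  expect_error(gss_label_subject(tgt$activation, pop$db$atlases, c(1, 2),
                                 cfg), "leakage")
})

test_that("identical atlases at threshold 0 reproduce the shared labels", {
  pop <- zero_var_pop()
  cfg <- experiment_config(n_selected_atlases = 0L)
  tgt <- pop$db$atlases[[10]]
  refs <- pop$db$atlases[1:9]
  out <- gss_label_subject(tgt$activation, refs, c(1, 2), cfg, threshold = 0)
  # shared labels restricted to the target's supra-threshold voxels
  for (l in c(1L, 2L))
    expect_gte(dice_coefficient(label_voxels(out, l),
                                label_voxels(tgt$labels, l)), 0.95)
})

test_that("GSS+AS differs from GSS only through the atlas subset", {
  pop <- gss_cohort()
  cfg <- experiment_config(n_selected_atlases = 5L)
  tgt <- pop$db$atlases[[12]]
  refs <- pop$db$atlases[1:11]
  db_refs <- atlas_db(refs)
  m <- build_collective_mask(db_refs, c(1, 2))
  with_sel <- gss_label_subject(tgt$activation, refs, c(1, 2), cfg, 0.1,
                                use_selection = TRUE, mask = m)
  ranked <- rank_atlases(tgt$activation, db_refs, m, cfg)
  keep <- select_atlases(ranked, 5)
  manual_subset <- gss_label_subject(tgt$activation, db_refs$atlases[keep],
                                     c(1, 2), cfg, 0.1)
  expect_identical(with_sel$labels, manual_subset$labels)
})

test_that("multi-threshold accuracy is the across-threshold mean of per-threshold Dice", {
  pop <- gss_cohort()
  cfg <- experiment_config(n_selected_atlases = 5L)
  tgt <- pop$db$atlases[[12]]
  refs <- pop$db$atlases[1:11]
  res <- gss_multi_threshold_accuracy(tgt$activation, tgt$labels, refs,
                                      c(1, 2), cfg)
  per_thr <- vapply(cfg$mpm_thresholds, function(thr) {
    auto <- gss_label_subject(tgt$activation, refs, c(1, 2), cfg, thr)
    vapply(c(1L, 2L), function(l)
      dice_coefficient(label_voxels(auto, l), label_voxels(tgt$labels, l)),
      numeric(1))
  }, numeric(2))
  expect_equal(res$dice, rowMeans(per_thr), tolerance = 1e-12)
})
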