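rand_prob_map <- function(grid, classes, voxels, seed, id = "s") {
  p <- with_seed_local(seed,
                       matrix(runif(length(voxels) * length(classes)),
                              length(voxels)))
  p <- p / rowSums(p)
  prob_label_map(grid, classes, voxels, p, id)
}

test_that("fusion is the voxelwise mean with class alignment", {
  g <- vol_grid(c(4, 4, 2))
  expect_error(fuse_prob_maps(list()), "empty")
  p1 <- prob_label_map(g, c(0L, 1L), 5L, matrix(c(1, 0), 1), "s")
  expect_equal(fuse_prob_maps(list(p1))$probs, p1$probs)     # mean of one
  p2 <- prob_label_map(g, c(0L, 1L), 5L, matrix(c(0, 1), 1), "s")
  f <- fuse_prob_maps(list(p1, p2))
  expect_equal(as.vector(f$probs), c(0.5, 0.5))
  # 15 random maps match the elementwise mean oracle to 1e-12
  vox <- c(3L, 9L, 17L, 30L)
  maps <- lapply(1:15, function(i) rand_prob_map(g, c(0L, 1L, 2L), vox, i))
  f15 <- fuse_prob_maps(maps)
  oracle <- Reduce(`+`, lapply(maps, `[[`, "probs")) / 15
  expect_equal(f15$probs, oracle, tolerance = 1e-12)
  # permutation invariance over atlases
  f15b <- fuse_prob_maps(rev(maps))
  expect_equal(f15$probs, f15b$probs, tolerance = 1e-12)
  # class alignment: a map missing class 2 contributes zero probability
  f2 <- fuse_prob_maps(list(p1, rand_prob_map(g, c(0L, 1L, 2L), 5L, 99)))
  expect_identical(f2$classes, c(0L, 1L, 2L))
})

test_that("majority vote is argmax with background-first then lowest-id ties", {
  g <- vol_grid(c(4, 4, 2))
  p <- prob_label_map(g, c(0L, 1L, 2L), c(1L, 2L, 3L),
                      rbind(c(0.6, 0.3, 0.1),
                            c(0.25, 0.5, 0.25),
                            c(0.2, 0.4, 0.4)), "s")
  v <- majority_vote(p)
  expect_identical(as.vector(v$labels[1:3]), c(0L, 1L, 1L))  # tie -> lowest id
  ptie <- prob_label_map(g, c(0L, 1L), 7L, matrix(c(0.5, 0.5), 1), "s")
  expect_identical(majority_vote(ptie)$labels[7], 0L)        # background first
  # 1000 random probability vectors equal an exhaustive argmax-with-tie oracle
  classes <- c(0L, 1L, 2L, 3L)
  probs <- with_seed_local(4, {
    m <- matrix(sample(0:4, 4000, replace = TRUE), ncol = 4)  # ties likely
    m[rowSums(m) == 0, 1] <- 1
    m / rowSums(m)
  })
  g2 <- vol_grid(c(10, 10, 10))
  pm <- prob_label_map(g2, classes, seq_len(nrow(probs)), probs, "s")
  got <- as.vector(majority_vote(pm)$labels[seq_len(nrow(probs))])
  oracle <- apply(probs, 1, function(row) {
    best <- which(row == max(row))
    classes[min(best)]     # class list is bg-first then ascending ids
  })
  expect_identical(got, as.integer(oracle))
})

test_that("voted labels occur only at candidate voxels", {
  pop <- small_pop()
  m <- build_collective_mask(pop$db, c(1, 2))
  cfg <- experiment_config(n_selected_atlases = 0L)
  tgt <- pop$db$atlases[[8]]
  refs <- atlas_db(pop$db$atlases[1:7])
  out <- mal_label_subject(tgt$activation, refs, c(1, 2), cfg)
  cand <- candidate_voxels(tgt$activation, m, cfg$z_threshold)
  labeled <- which(as.vector(out$labels) != 0L)
  expect_true(all(labeled %in% cand))
})

test_that("image-based transfer matches the voxelwise plurality-count oracle", {
  g <- vol_grid(c(16, 16, 8))
  mk <- function(id, shift) {
    vox <- cuboid_voxels(g, c(3, 8) + shift, c(3, 8), c(2, 5))
    z <- array(0, g$shape); z[vox] <- 5
    lab <- array(0L, g$shape); lab[vox] <- 1L
    atlas(activation_map(g, z, id), label_map(g, lab, subject_id = id),
          quiet = TRUE)
  }
  atlases <- lapply(0:9, function(i) mk(sprintf("s%02d", i), i %% 4))
  db <- atlas_db(atlases)
  m <- build_collective_mask(db, 1L)
  cfg <- experiment_config()
  tgt <- atlases[[1]]$activation
  got <- image_based_transfer(atlases[-1], tgt, m, cfg, labels = 1L)
  # counting oracle: per candidate voxel, plurality over atlas labels with
  # background-first tie rule
  cand <- candidate_voxels(tgt, m, cfg$z_threshold)
  lab_mat <- vapply(atlases[-1], function(a)
    as.vector(a$labels$labels)[cand], integer(length(cand)))
  oracle <- apply(lab_mat, 1, function(v) {
    n1 <- sum(v == 1L); n0 <- sum(v == 0L)
    if (n1 > n0) 1L else 0L
  })
  expect_identical(as.vector(got$labels)[cand], oracle)
  # single atlas: transfer restricted to the target's candidate voxels
  one <- image_based_transfer(atlases[2], tgt, m, cfg, labels = 1L)
  expect_identical(as.vector(one$labels)[cand],
                   as.vector(atlases[[2]]$labels$labels)[cand])
  expect_true(all(one$labels[-cand] == 0L))
  expect_error(image_based_transfer(list(), tgt, m, cfg, labels = 1L),
               "empty")
})

test_that("end-to-end MAL labeling: identical-cohort recovery, N=1 equivalence, determinism", {
  pop <- zero_var_pop()
  cfg <- experiment_config(n_selected_atlases = 0L)
  tgt <- pop$db$atlases[[10]]
  refs <- atlas_db(pop$db$atlases[1:9])
  out <- mal_label_subject(tgt$activation, refs, c(1, 2), cfg)
  for (l in c(1L, 2L))
    expect_gte(dice_coefficient(label_voxels(out, l),
                                label_voxels(tgt$labels, l)), 0.95)
  # determinism: bitwise-identical label volumes on rerun
  out2 <- mal_label_subject(tgt$activation, refs, c(1, 2), cfg)
  expect_identical(out$labels, out2$labels)
  # N = 1 equals the single best atlas's voted prediction
  cfg1 <- experiment_config(n_selected_atlases = 1L)
  m <- build_collective_mask(refs, c(1, 2))
  ranked <- rank_atlases(tgt$activation, refs, m, cfg1)
  best <- ranked$subject_id[1]
  enc <- train_atlas_encoder(refs$atlases[[best]], m, c(1, 2), cfg1)
  solo <- majority_vote(predict_prob_map(enc, tgt$activation, m, cfg1,
                                         labels = c(1L, 2L)))
  multi <- mal_label_subject(tgt$activation, refs, c(1, 2), cfg1)
  expect_identical(multi$labels, solo$labels)
  # N exceeding the database size errors
  expect_error(mal_label_subject(tgt$activation, refs, c(1, 2),
                                 experiment_config(n_selected_atlases = 40L)),
               "exceeds")
})
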