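test_that("Dice coefficient: identities, empties and counting oracle", {
  expect_equal(dice_coefficient(c(3L, 9L), c(3L, 9L)), 1.0)
  expect_equal(dice_coefficient(c(1L, 2L), c(2L, 3L)), 0.5)
  expect_true(is.na(dice_coefficient(integer(0), integer(0))))
  expect_equal(dice_coefficient(integer(0), c(1L, 2L)), 0)
  for (i in 1:10) {
    a <- with_seed_local(i, sample(500L, 50L))
    b <- with_seed_local(i + 99, sample(500L, 50L))
    oracle <- 2 * sum(a %in% b) / (length(a) + length(b))
    expect_equal(dice_coefficient(a, b), oracle)
  }
})

test_that("peak consistency matches a brute-force argmax-and-distance oracle", {
  g <- vol_grid(c(10, 10, 6))
  z <- array(with_seed_local(21, rnorm(prod(g$shape), 3)), g$shape)
  act <- activation_map(g, z, "s")
  mk_lab <- function(vox) {
    l <- array(0L, g$shape); l[vox] <- 1L
    label_map(g, l, subject_id = "s")
  }
  vox_m <- cuboid_voxels(g, c(2, 5), c(2, 5), c(1, 3))
  manual <- mk_lab(vox_m)
  # identical regions match
  expect_true(peak_consistency(manual, manual, act, 1L))
  # auto region excluding the manual peak, radius 0 -> no match
  pk <- vox_m[which.max(as.vector(z)[vox_m])]
  auto_off <- mk_lab(setdiff(vox_m, pk))
  expect_false(peak_consistency(auto_off, manual, act, 1L, radius_mm = 0))
  # random regions vs exhaustive oracle, radius 0 and 6 mm
  for (i in 1:8) {
    va <- with_seed_local(300 + i, sample(prod(g$shape), 40))
    vm <- with_seed_local(400 + i, sample(prod(g$shape), 40))
    auto <- mk_lab(va); man <- mk_lab(vm)
    argmax_lex <- function(vox) {
      cc <- voxel_coords(g, vox)
      vox <- vox[order(cc[, 1], cc[, 2], cc[, 3])]
      vox[which.max(as.vector(z)[vox])]
    }
    pa <- argmax_lex(va); pm <- argmax_lex(vm)
    d <- sqrt(sum((voxel_to_mm(g, voxel_coords(g, pa)) -
                     voxel_to_mm(g, voxel_coords(g, pm)))^2))
    expect_identical(peak_consistency(auto, man, act, 1L, 0), pa == pm)
    expect_identical(peak_consistency(auto, man, act, 1L, 6),
                     pa == pm || d <= 6)
  }
  # empty manual region is undefined; empty auto region is FALSE
  expect_true(is.na(peak_consistency(manual, mk_lab(integer(0)), act, 1L)))
  expect_false(peak_consistency(mk_lab(integer(0)), manual, act, 1L))
})

test_that("LOSOCV bookkeeping: record counts, leakage, identical-cohort recovery", {
  pop <- zero_var_pop()
  cfg <- experiment_config(n_selected_atlases = 0L)
  prep <- zero_var_prep()
  rec <- losocv(pop$db, c(1, 2), cfg, methods = "mal", prep = prep)
  expect_equal(nrow(rec), 10 * 2)          # n subjects x |labels|
  expect_true(all(rec$method == "mal"))
  expect_true(all(rec$dice >= 0 & rec$dice <= 1))
  # 2-subject identical database: Dice ~ 1 both folds
  two <- atlas_db(pop$db$atlases[1:2])
  rec2 <- losocv(two, c(1, 2), cfg, methods = "mal")
  expect_gte(min(rec2$dice), 0.95)
  # n_selected_atlases larger than fold errors
  expect_error(losocv(two, c(1, 2),
                      experiment_config(n_selected_atlases = 5L),
                      methods = "mal"),
               "exceeds")
})

test_that("gss and gss_as LOSOCV records differ only via the atlas subset", {
  pop <- cached_fixture("gss_cohort", function()
    generate_population(population_spec(n_subjects = 12, seed = 19)))
  cfg <- experiment_config(n_selected_atlases = 5L)
  rec <- losocv(pop$db, c(1, 2), cfg, methods = c("gss", "gss_as"))
  expect_equal(nrow(rec), 12 * 2 * 2)
  # with selection the group maps come from 5 atlases, without from 11
  expect_true(all(rec$n_atlases[rec$method == "gss"] == 11))
  expect_true(all(rec$n_atlases[rec$method == "gss_as"] == 5))
  # controlled diff: forcing the subset size to the whole fold makes the
  # two methods coincide
  cfg_all <- experiment_config(n_selected_atlases = 11L)
  rec_all <- losocv(pop$db, c(1, 2), cfg_all, methods = c("gss", "gss_as"))
  g1 <- rec_all[rec_all$method == "gss", c("target_subject", "roi_label", "dice")]
  g2 <- rec_all[rec_all$method == "gss_as", c("target_subject", "roi_label", "dice")]
  expect_equal(g1$dice, g2$dice)
})

test_that("pairwise encoded similarity: identical atlases give 1, disjoint raw labels give 0", {
  a <- two_cuboid_atlas()
  m <- make_mask(a$activation$grid, full = TRUE)
  res <- pairwise_encoded_similarity(a, a, m, c(1, 2))
  expect_equal(res$dice_original, c(1, 1))
  expect_equal(res$dice_encoded, c(1, 1))
  b <- two_cuboid_atlas("cubB", shift = c(6, 0, 0))  # disjoint from a
  res2 <- pairwise_encoded_similarity(a, b, m, c(1, 2))
  expect_equal(res2$dice_original[1], 0)
})

test_that("Steiger's Z: identity, sign, and agreement with the textbook formula", {
  st0 <- steiger_z(0.6, 0.6, 0.8, 50)
  expect_equal(st0$z, 0); expect_equal(st0$p, 1)
  # manual means perfectly recovered by auto1, noisy auto2 -> Z > 0
  m <- with_seed_local(8, rnorm(30, 5))
  a2 <- m + with_seed_local(9, rnorm(30, 0, 2))
  res <- intensity_concordance(m, m + with_seed_local(10, rnorm(30, 0, 1e-8)),
                               a2)
  expect_gt(res$steiger_z, 0)
  # textbook-formula oracle on a fixed triple
  r12 <- 0.7; r13 <- 0.5; r23 <- 0.6; n <- 50
  rbar <- (r12 + r13) / 2
  psi <- r23 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)
  zo <- (atanh(r12) - atanh(r13)) * sqrt(n - 3) /
    sqrt(2 - 2 * psi / (1 - rbar^2)^2)
  expect_equal(steiger_z(r12, r13, r23, n)$z, zo, tolerance = 1e-12)
  expect_error(steiger_z(0.5, 0.4, 0.3, 3), "n >= 4")
  expect_error(intensity_concordance(rep(1, 10), rnorm(10), rnorm(10)),
               "constant")
  expect_error(intensity_concordance(rnorm(10), rnorm(10), rnorm(9)),
               "equal length")
})

test_that("intensity concordance excludes incomplete subjects pairwise", {
  m <- c(NA, 1, 2, 3, 4, 5, 6)
  a1 <- c(1, 2, 3, 4, 5, NA, 7)
  a2 <- c(1, 1.5, 3.5, 4, 4.5, 6, 6.5)
  res <- intensity_concordance(m, a1, a2)
  expect_equal(res$n, 5)
})

test_that("forest-parameter grid has the right shape and a 1x1 grid equals plain LOSOCV", {
  pop <- small_pop()
  cfg <- experiment_config(n_selected_atlases = 0L,
                           forest = forest_params(10, 10, seed = 3))
  m11 <- forest_param_grid(pop$db, c(1, 2), cfg, t_values = 10, d_values = 10)
  expect_identical(dim(m11), c(1L, 1L))
  rec <- losocv(pop$db, c(1, 2), cfg, methods = "mal")
  expect_equal(m11[1, 1], mean(rec$dice, na.rm = TRUE), tolerance = 1e-12)
  m23 <- forest_param_grid(pop$db, c(1, 2), cfg, t_values = c(5, 10),
                           d_values = c(4, 8, 12))
  expect_identical(dim(m23), c(2L, 3L))
})
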