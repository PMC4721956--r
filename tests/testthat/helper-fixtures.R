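# Programmatic fixtures shared across the suite. Expensive cohorts are
# built once per test run and memoised in a session cache.

.fixture_cache <- new.env(parent = emptyenv())

with_seed_local <- function(seed, expr) withr::with_seed(seed, expr)

cached_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# hand-built collective mask over explicit voxel indices
make_mask <- function(grid, voxels = NULL, full = FALSE, source_labels = 1L) {
  m <- array(full, grid$shape)
  if (!is.null(voxels)) m[voxels] <- TRUE
  structure(list(grid = grid, mask = m, source_labels = source_labels),
            class = "collective_mask")
}

# a cuboid's linear voxel indices: 0-based inclusive coordinate ranges
cuboid_voxels <- function(grid, xr, yr, zr) {
  cc <- as.matrix(expand.grid(x = xr[1]:xr[2], y = yr[1]:yr[2],
                              z = zr[1]:zr[2]))
  voxel_index(grid, cc)
}

# atlas with two well-separated cuboid fROIs (gap >= 5 voxels), constant
# activation 5 inside, 0 outside
two_cuboid_atlas <- function(subject_id = "cubA", shift = c(0, 0, 0)) {
  g <- vol_grid(c(20, 20, 10), id = "cuboid")
  v1 <- cuboid_voxels(g, c(2, 6) + shift[1], c(2, 6) + shift[2],
                      c(2, 6) + shift[3])
  v2 <- cuboid_voxels(g, c(13, 17) + shift[1], c(13, 17) + shift[2],
                      c(2, 6) + shift[3])
  z <- array(0, g$shape); z[c(v1, v2)] <- 5
  lab <- array(0L, g$shape); lab[v1] <- 1L; lab[v2] <- 2L
  atlas(activation_map(g, z, subject_id),
        label_map(g, lab, c("1" = "A", "2" = "B"), subject_id),
        quiet = TRUE)
}

# --- memoised cohorts at the study conditions -------------------------

# zero inter-subject variability, 10 subjects, 2 ROIs
zero_var_pop <- function() cached_fixture("zero_var_pop", function() {
  generate_population(population_spec(
    n_subjects = 10, translation_sd_mm = 0, scale_sd = 0,
    shape_jitter_sd = 0, z_peak_sd = 0, seed = 11))
})

zero_var_prep <- function() cached_fixture("zero_var_prep", function() {
  cfg <- experiment_config(n_selected_atlases = 0L)
  mal_precompute(zero_var_pop()$db, c(1, 2), cfg)
})

# clustered cohort: n = 60, translation sd 4 mm, 2 latent prototypes
# (boundary-clipping warnings at this displacement are by design)
clustered_pop <- function() cached_fixture("clustered_pop", function() {
  spec <- suppressWarnings(population_spec(
    n_subjects = 60, translation_sd_mm = 4, n_prototypes = 2, seed = 42))
  generate_population(spec)
})

clustered_cfg <- function() experiment_config(n_selected_atlases = 40L)

clustered_prep <- function() cached_fixture("clustered_prep", function() {
  mal_precompute(clustered_pop()$db, c(1, 2), clustered_cfg())
})

# small generic cohort for cheap integration tests
small_pop <- function() cached_fixture("small_pop", function() {
  generate_population(population_spec(n_subjects = 8, seed = 5))
})
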