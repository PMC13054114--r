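test_that("scene generation is a pure function of the spec", {
  spec <- scene_spec(seed = 17, n_particle_pixels = 300)
  a <- generate_scene(spec)
  b <- generate_scene(spec)
  expect_identical(a$scene$channels, b$scene$channels)
  expect_identical(a$truth$distances_um, b$truth$distances_um)
  expect_identical(a$truth$particle_mask, b$truth$particle_mask)
})

test_that("scene generation does not disturb the caller's RNG stream", {
  set.seed(1)
  x1 <- runif(1)
  set.seed(1)
  invisible(generate_scene(scene_spec(seed = 99, n_particle_pixels = 10)))
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("ground truth is self-consistent with the exact distance map", {
  gen <- generate_scene(scene_spec(seed = 2, n_particle_pixels = 500))
  t <- gen$truth
  expect_true(all(t$nuclei_mask[t$particle_mask] | TRUE))  # masks align
  expect_true(all(t$particle_mask <= t$cell_mask))
  um <- to_microns(compute_distance_map(t$nuclei_mask), 0.15537)
  expect_equal(um$grid[t$particle_mask], t$distances_um, tolerance = 1e-9)
})

test_that("degenerate mixtures place all pixels in the requested bin", {
  gen <- generate_scene(scene_spec(seed = 3, n_particle_pixels = 200,
                                   radial_weights = c(1, 0, 0)))
  expect_true(all(gen$truth$distances_um < 5))
  gen2 <- generate_scene(scene_spec(seed = 3, n_particle_pixels = 200,
                                    radial_weights = c(0, 0, 1)))
  expect_true(all(gen2$truth$distances_um >= 10))
})

test_that("zero particles yields an empty mask and background channel", {
  gen <- generate_scene(scene_spec(seed = 4, n_particle_pixels = 0,
                                   noise_sd = 0))
  expect_equal(sum(gen$truth$particle_mask), 0L)
  expect_true(all(gen$scene$channels$particle == 5))
})

test_that("infeasible geometry raises a generation error", {
  expect_error(
    generate_scene(scene_spec(seed = 1, image_shape = c(64L, 64L),
                              n_cells = 4L)),
    "infeasible geometry")
})

test_that("shifting radial weight outward increases distance and periphery", {
  mean_d <- numeric(3)
  peri3 <- numeric(3)
  ws <- list(c(0.8, 0.1, 0.1), c(0.4, 0.3, 0.3), c(0.1, 0.2, 0.7))
  for (i in 1:3) {
    gen <- generate_scene(scene_spec(seed = 7, n_particle_pixels = 2000,
                                     radial_weights = ws[[i]]))
    mean_d[i] <- mean(gen$truth$distances_um)
    peri3[i] <- gen$truth$true_bin_pct[3]
  }
  expect_true(all(diff(mean_d) > 0))
  expect_true(all(diff(peri3) > 0))
})

test_that("micrograph truth table reflects the requested population", {
  spec <- micrograph_spec(seed = 8, n_particles = 50)
  gen <- generate_micrograph(spec)
  expect_equal(nrow(gen$truth), 50L)
  expect_true(all(gen$truth$diameter_um > 0))
  # identical diameters when sd = 0
  spec0 <- micrograph_spec(seed = 8, n_particles = 10,
                           diameter_um = c(mean = 0.1, sd = 0))
  gen0 <- generate_micrograph(spec0)
  expect_equal(length(unique(gen0$truth$diameter_um)), 1L)
  # a single circular particle has continuous circularity exactly 1
  spec1 <- micrograph_spec(seed = 1, n_particles = 1,
                           eccentricity_range = c(0, 0))
  expect_equal(generate_micrograph(spec1)$truth$circularity, 1)
  # determinism
  expect_identical(generate_micrograph(spec)$truth, gen$truth)
})

test_that("pooled truth-table population recovers the generating moments", {
  truths <- lapply(1:5, function(s)
    generate_micrograph(micrograph_spec(seed = s, n_particles = 100))$truth)
  d_nm <- unlist(lapply(truths, function(t) t$diameter_um)) * 1000
  expect_length(d_nm, 500L)
  expect_equal(mean(d_nm), 99, tolerance = 1 / 99)       # within 1 nm
  expect_equal(sd(d_nm), 5, tolerance = 1 / 5)           # within 1 nm
})

test_that("recovery differences shrink with more particle pixels", {
  err <- vapply(c(500L, 5000L), function(n) {
    rep <- recovery_report(scene_spec(seed = 31, n_particle_pixels = n,
                                      noise_sd = 0,
                                      dilate_particles = TRUE))
    max(rep$abs_diff_pct)
  }, numeric(1))
  expect_lte(err[2], err[1] + 0.5)  # allow sampling jitter at equality
  expect_lte(err[2], 3)
})
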