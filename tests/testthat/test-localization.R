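test_that("distance map is exact on analytic single-pixel case", {
  m <- matrix(FALSE, 5, 5)
  m[3, 3] <- TRUE
  dm <- compute_distance_map(m)
  expect_equal(dm$units, "px")
  expect_equal(dm$grid[3, 3], 0)
  expect_equal(dm$grid[3, 5], 2)
  expect_equal(dm$grid[1, 1], 2 * sqrt(2))
})

test_that("distance map equals the exhaustive oracle on random grids", {
  set.seed(42)
  for (i in 1:25) {
    nr <- sample(4:16, 1); nc <- sample(4:16, 1)
    m <- matrix(runif(nr * nc) < 0.15, nr, nc)
    if (!any(m)) m[sample(nr * nc, 1)] <- TRUE
    dm <- compute_distance_map(m)
    expect_equal(dm$grid, brute_force_edt(m), ignore_attr = TRUE)
  }
})

test_that("empty nuclei mask raises the no-nuclei error", {
  expect_error(compute_distance_map(matrix(FALSE, 4, 4)), "no-nuclei")
})

test_that("micron conversion applies the confocal scale factor", {
  m <- matrix(FALSE, 3, 3); m[1, 1] <- TRUE
  dm <- compute_distance_map(m)
  um <- to_microns(dm)                      # default calibration
  expect_equal(um$units, "um")
  expect_equal(um$grid[1, 2], 0.15537)      # 1 px
  expect_equal(um$grid[1, 1], 0)            # 0 stays 0
  expect_equal(to_microns(dm, 1)$grid, dm$grid)  # unit scale is identity
  expect_error(to_microns(dm, -1), "positive")
  expect_error(to_microns(um), "pixel units")
})

test_that("particle distances are a direct per-pixel lookup", {
  m <- matrix(FALSE, 4, 4); m[1, 1] <- TRUE
  um <- to_microns(compute_distance_map(m), 1)
  p <- matrix(FALSE, 4, 4)
  p[1, 1] <- TRUE; p[1, 4] <- TRUE; p[4, 1] <- TRUE
  d <- particle_distances(um, p)
  expect_setequal(d, c(0, 3, 3))
  expect_length(particle_distances(um, matrix(FALSE, 4, 4)), 0)
  expect_error(particle_distances(compute_distance_map(m), p), "microns")
})

test_that("synthetic ground-truth distances match the pipeline lookup", {
  gen <- generate_scene(scene_spec(seed = 9, n_particle_pixels = 400))
  um <- to_microns(compute_distance_map(gen$truth$nuclei_mask),
                   gen$scene$pixel_size_um)
  d <- particle_distances(um, gen$truth$particle_mask)
  expect_equal(sort(d), sort(gen$truth$distances_um), tolerance = 1e-12)
})

test_that("radial histogram bins are half-open and normalize to 100", {
  h <- radial_histogram(c(0, 0, 0), bin_width_um = 0.5, max_edge_um = 2)
  expect_equal(h$percent[1], 100)
  h2 <- radial_histogram(c(0.25, 0.75), bin_width_um = 0.5, max_edge_um = 2)
  expect_equal(h2$percent[1:2], c(50, 50))
  # boundary value 0.5 goes to the second bin
  h3 <- radial_histogram(0.5, bin_width_um = 0.5, max_edge_um = 2)
  expect_equal(h3$counts[2], 1L)
  # open-ended final bin catches everything beyond max_edge
  h4 <- radial_histogram(c(1, 99), bin_width_um = 0.5, max_edge_um = 2)
  expect_equal(h4$counts[length(h4$counts)], 1L)
  expect_equal(sum(h4$percent), 100)
  # empty input: flagged, all-zero
  h5 <- radial_histogram(numeric(0))
  expect_equal(h5$n, 0L)
  expect_true(all(h5$counts == 0))
})

test_that("uniform draws fill fixed-width bins evenly", {
  set.seed(123)
  d <- runif(10000, 0, 10)
  h <- radial_histogram(d, bin_width_um = 1, max_edge_um = 10)
  expect_true(all(abs(h$percent[1:10] - 10) <= 1))
  expect_equal(sum(h$counts), 10000L)
})

test_that("three-bin summary follows the half-open convention", {
  s <- bin_summary(c(2.5, 7.5, 12.5))
  expect_equal(c(s$perinuclear_pct, s$intermediate_pct, s$peripheral_pct),
               rep(100 / 3, 3))
  expect_equal(s$perinuclear_pct + s$intermediate_pct + s$peripheral_pct,
               100, tolerance = 1e-9)
  s0 <- bin_summary(rep(0, 5))
  expect_equal(s0$perinuclear_pct, 100)
  sb <- bin_summary(5)     # boundary: exactly 5 um is intermediate
  expect_equal(sb$intermediate_pct, 100)
  se <- bin_summary(numeric(0))
  expect_true(se$empty)
  expect_equal(se$n_pixels, 0L)
})

test_that("binning commutes with micron scaling (scale equivariance)", {
  set.seed(5)
  d_px <- runif(500, 0, 120)
  s <- 0.15537
  a <- bin_summary(d_px * s, edges = c(5, 10))
  b <- bin_summary(d_px, edges = c(5, 10) / s)
  expect_equal(c(a$perinuclear_pct, a$intermediate_pct, a$peripheral_pct),
               c(b$perinuclear_pct, b$intermediate_pct, b$peripheral_pct))
})

test_that("aggregate_conditions groups by condition with sample SD", {
  mk <- function(peri, dose, tp, id) {
    rest <- (100 - peri) / 2
    bin_summary(c(rep(2, peri), rep(7, rest), rep(12, rest)),
                meta = list(image_id = id, dosage_label = dose,
                            timepoint_h = tp))
  }
  s1 <- mk(40, "high", 3, "a")
  s2 <- mk(60, "high", 3, "b")
  s3 <- mk(80, "med", 3, "c")
  tab <- aggregate_conditions(list(s1, s2, s3))
  expect_equal(nrow(tab), 2L)
  hi <- tab[tab$dosage_label == "high", ]
  expect_equal(hi$perinuclear_mean, 50)
  expect_equal(hi$perinuclear_sd, sd(c(40, 60)))
  expect_equal(hi$n_images, 2L)
  # one image per group: SD defined as 0
  expect_equal(tab[tab$dosage_label == "med", "perinuclear_sd"], 0)
  # order invariance
  tab2 <- aggregate_conditions(list(s3, s2, s1))
  expect_equal(tab, tab2)
  # empty summaries dropped with warning
  expect_warning(
    tab3 <- aggregate_conditions(list(s1, s2, s3, bin_summary(numeric(0)))),
    "excluded")
  expect_equal(tab3, tab)
})
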