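test_that("segment_nuclei recovers disjoint disks and errors on flat input", {
  shape <- c(64, 64)
  truth <- draw_disk(shape, 18, 18, 12, half = 0) |
    draw_disk(shape, 46, 46, 12, half = 0)
  sc <- scene_from_masks(truth, matrix(TRUE, 64, 64), matrix(FALSE, 64, 64))
  lm <- segment_nuclei(sc)
  expect_equal(lm$n_objects, 2L)
  areas <- tabulate(lm$grid[lm$grid > 0], nbins = 2)
  expect_true(all(abs(areas - pi * 12^2) / (pi * 12^2) < 0.05))

  flat <- scene(list(nuclei = matrix(3, 16, 16)))
  expect_error(segment_nuclei(flat), "no-contrast")
})

test_that("touching disks merge into one object, matching the BFS oracle", {
  shape <- c(48, 48)
  truth <- draw_disk(shape, 24, 18, 10) | draw_disk(shape, 24, 34, 10)
  sc <- scene_from_masks(truth, matrix(TRUE, 48, 48), matrix(FALSE, 48, 48))
  lm <- segment_nuclei(sc)
  expect_equal(lm$n_objects, 1L)
  # oracle: components of the thresholded grid itself
  expect_length(brute_force_component_areas(lm$grid > 0), 1L)
})

test_that("nucleus count matches generated count on high-SNR scenes", {
  for (seed in 1:3) {
    gen <- generate_scene(scene_spec(seed = seed, n_particle_pixels = 0))
    lm <- segment_nuclei(gen$scene)
    expect_equal(lm$n_objects, 2L)
  }
})

test_that("segment_cells covers nuclei and falls back to full frame", {
  gen <- generate_scene(scene_spec(seed = 3, n_particle_pixels = 0))
  nuc <- segment_nuclei(gen$scene)
  cm <- segment_cells(gen$scene, nuclei = nuc)
  expect_true(all(cm$grid[nuc$grid > 0]))
  # Jaccard against the generator's true cell mask
  jac <- sum(cm$grid & gen$truth$cell_mask) / sum(cm$grid | gen$truth$cell_mask)
  expect_gte(jac, 0.9)

  flat <- scene(list(cell = matrix(0, 8, 8)))
  expect_warning(full <- segment_cells(flat), "full-frame")
  expect_true(all(full$grid))
  uniform <- scene(list(cell = matrix(100, 8, 8)))
  expect_warning(full2 <- segment_cells(uniform), "full-frame")
  expect_true(all(full2$grid))
})

test_that("segment_particles recovers puncta with low false positives", {
  gen <- generate_scene(scene_spec(seed = 11, n_particle_pixels = 500))
  pm <- segment_particles(gen$scene)
  truth <- gen$truth$particle_mask
  recovered <- sum(pm$grid & truth) / sum(truth)
  fp <- sum(pm$grid & !truth) / sum(!truth)
  expect_gte(recovered, 0.95)
  expect_lte(fp, 0.01)
})

test_that("segment_particles handles controls and singletons", {
  empty <- scene(list(particle = matrix(0, 10, 10)))
  expect_equal(sum(segment_particles(empty)$grid), 0L)

  g <- matrix(0, 10, 10)
  g[4, 7] <- 255
  single <- scene(list(particle = g))
  pm <- segment_particles(single)
  expect_identical(which(pm$grid), which(g > 0))
})

test_that("clean_particle_mask gates, filters by area and is idempotent", {
  p <- matrix(FALSE, 12, 12)
  p[1, 1] <- TRUE              # area 1
  p[6, 12] <- TRUE             # area 1
  p[4:6, 4:6] <- TRUE          # area 9
  cells <- matrix(TRUE, 12, 12)
  cl <- clean_particle_mask(binary_mask(p), binary_mask(cells, "cell"),
                            min_component_px = 2)
  expect_equal(sum(cl$grid), 9L)
  expect_equal(brute_force_component_areas(cl$grid), 9L)

  # gating: everything outside the cell mask disappears
  outside <- clean_particle_mask(binary_mask(p),
                                 binary_mask(matrix(FALSE, 12, 12), "cell"))
  expect_equal(sum(outside$grid), 0L)

  # idempotence and containment
  cl2 <- clean_particle_mask(cl, binary_mask(cells, "cell"),
                             min_component_px = 2)
  expect_identical(cl2$grid, cl$grid)
  expect_true(all(!cl$grid | (p & cells)))
})

test_that("segmentation is deterministic for identical input", {
  gen <- generate_scene(scene_spec(seed = 5, n_particle_pixels = 200))
  a <- segment_nuclei(gen$scene)
  b <- segment_nuclei(gen$scene)
  expect_identical(a$grid, b$grid)
  expect_identical(segment_particles(gen$scene)$grid,
                   segment_particles(gen$scene)$grid)
})
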