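#' @title Ground-truthed synthetic scenes and micrographs
#' @description Generators that emulate the pipeline's two input classes --
#'   multichannel confocal scenes with known nuclei, cell areas and particle
#'   pixels placed by a three-bin radial mixture, and dry-state
#'   micrograph-like fields of near-circular particles with a known size
#'   distribution -- together with exact ground truth, so every pipeline
#'   stage can be validated against known answers.
#' @name synthetic_data
NULL

# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a synthetic confocal scene
#'
#' The scene emulates the structure of a confocal field of view: a dark
#' background, one or more round cells delineated by a diffuse cytoskeletal
#' channel, a bright elliptical nucleus inside each cell, and punctate
#' particle-positive pixels placed cell-interior-only according to a
#' three-bin mixture over distance from the nearest nucleus.
#'
#' @param seed RNG seed; the scene is a pure function of the spec (seed
#'   included).
#' @param image_shape `(rows, cols)` in pixels.
#' @param pixel_size_um microns per pixel.
#' @param n_cells number of non-overlapping round cells.
#' @param nucleus_radius_px `(min, max)` equivalent radius of the elliptical
#'   nuclei.
#' @param cell_radius_px `(min, max)` cell radius; must exceed the nucleus
#'   radius.
#' @param n_particle_pixels number of distinct particle-positive pixels to
#'   place.
#' @param radial_weights mixture weights `(p1, p2, p3)` over the distance
#'   bins `[0, e1)`, `[e1, e2)`, `[e2, Inf)` microns; must sum to 1.
#' @param bin_edges_um the two bin edges in microns (default `c(5, 10)`).
#' @param noise_sd additive Gaussian noise SD (intensity units, clipped at
#'   0). The default 12 puts every channel at a signal-to-noise ratio of at
#'   least ~10.
#' @param intensities per-channel `c(bg, fg)` intensity levels.
#' @param dilate_particles if TRUE, each placed particle pixel is dilated to
#'   a 2x2 block (mask and ground truth included).
#' @param meta condition metadata passed through to the scene.
#' @return an object of class `SceneSpec`.
#' @export
scene_spec <- function(seed = 1L,
                       image_shape = c(512L, 512L),
                       pixel_size_um = 0.15537,
                       n_cells = 2L,
                       nucleus_radius_px = c(22, 30),
                       cell_radius_px = c(100, 120),
                       n_particle_pixels = 3000L,
                       radial_weights = c(0.60, 0.25, 0.15),
                       bin_edges_um = c(5, 10),
                       noise_sd = 12,
                       intensities = list(nuclei = c(bg = 10, fg = 200),
                                          cell = c(bg = 10, fg = 140),
                                          particle = c(bg = 5, fg = 150)),
                       dilate_particles = FALSE,
                       meta = list()) {
  if (length(radial_weights) != 3L || any(radial_weights < 0) ||
      abs(sum(radial_weights) - 1) > 1e-9)
    stop("'radial_weights' must be three non-negative values summing to 1")
  if (any(nucleus_radius_px <= 0) || any(cell_radius_px <= 0) ||
      diff(nucleus_radius_px) < 0 || diff(cell_radius_px) < 0)
    stop("radius ranges must be positive and non-decreasing")
  if (max(nucleus_radius_px) >= min(cell_radius_px))
    stop("nucleus radii must be smaller than cell radii")
  if (n_particle_pixels < 0) stop("'n_particle_pixels' must be >= 0")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be positive")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(seed = as.integer(seed), image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um, n_cells = as.integer(n_cells),
                 nucleus_radius_px = nucleus_radius_px,
                 cell_radius_px = cell_radius_px,
                 n_particle_pixels = as.integer(n_particle_pixels),
                 radial_weights = radial_weights, bin_edges_um = bin_edges_um,
                 noise_sd = noise_sd, intensities = intensities,
                 dilate_particles = isTRUE(dilate_particles), meta = meta),
            class = "SceneSpec")
}

# Pixel set of a filled ellipse: centre (cy, cx), semi-axes (a, b), angle th.
# Only the bounding box is evaluated.
.ellipse_mask <- function(shape, cy, cx, a, b, th = 0) {
  m <- matrix(FALSE, shape[1], shape[2])
  ext <- max(a, b) + 2
  r1 <- max(1L, floor(cy - ext)); r2 <- min(shape[1], ceiling(cy + ext))
  c1 <- max(1L, floor(cx - ext)); c2 <- min(shape[2], ceiling(cx + ext))
  if (r1 > r2 || c1 > c2) return(m)
  nr <- r2 - r1 + 1L; nc <- c2 - c1 + 1L
  rr <- matrix(r1:r2, nr, nc)
  cc <- matrix(c1:c2, nr, nc, byrow = TRUE)
  dy <- rr - cy; dx <- cc - cx
  u <- dy * cos(th) + dx * sin(th)
  v <- -dy * sin(th) + dx * cos(th)
  m[r1:r2, c1:c2] <- (u / a)^2 + (v / b)^2 <= 1
  m
}

# Place n non-overlapping discs fully inside the frame; radius drawn per
# disc from 'radius_range'. Errors after max_attempts rejections.
.place_discs <- function(shape, n, radius_range, margin = 2,
                         max_attempts = 1e4) {
  centers <- matrix(numeric(0), 0, 3)  # cy, cx, r
  attempts <- 0L
  while (nrow(centers) < n) {
    if (attempts >= max_attempts)
      stop("infeasible geometry: placed ", nrow(centers), " of ", n,
           " cells in ", max_attempts, " attempts")
    attempts <- attempts + 1L
    r <- stats::runif(1, radius_range[1], radius_range[2])
    lo <- r + margin
    if (shape[1] - r - margin <= lo || shape[2] - r - margin <= lo) {
      next
    }
    cy <- stats::runif(1, lo, shape[1] - r - margin)
    cx <- stats::runif(1, lo, shape[2] - r - margin)
    if (nrow(centers) > 0) {
      dd <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
      if (any(dd <= centers[, 3] + r + margin)) next
    }
    centers <- rbind(centers, c(cy, cx, r))
  }
  centers
}

#' Generate a synthetic confocal scene with exact ground truth
#'
#' Cells are placed as non-overlapping discs, each given one filled
#' elliptical nucleus near its centre. The exact Euclidean distance map of
#' the true nuclei mask (in microns) assigns every cell-interior pixel to a
#' distance bin; particle pixels are then sampled by first drawing a bin
#' from `radial_weights` (multinomial over the requested count) and then a
#' uniform pixel, without replacement, among the cell pixels of that bin. A
#' bin with no available pixels has its draws reassigned to the remaining
#' bins with a warning. Channels are rendered as background + foreground
#' levels plus additive Gaussian noise clipped at zero.
#'
#' @param spec a [scene_spec()].
#' @return a list with elements `scene` (a [scene()]) and `truth`, a
#'   `GroundTruth` list carrying the exact `nuclei_mask`, `cell_mask` and
#'   `particle_mask`, the per-particle-pixel `distances_um` (verified at
#'   generation against the exact distance transform), the per-pixel
#'   coordinates, the generating `radial_weights`, the realized
#'   `true_bin_pct`, and the seed.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  .with_seed(spec$seed, {
    shape <- spec$image_shape
    cells <- .place_discs(shape, spec$n_cells, spec$cell_radius_px)
    cell_mask <- matrix(FALSE, shape[1], shape[2])
    nuclei_mask <- matrix(FALSE, shape[1], shape[2])
    for (i in seq_len(nrow(cells))) {
      cy <- cells[i, 1]; cx <- cells[i, 2]; r <- cells[i, 3]
      cell_mask <- cell_mask | .ellipse_mask(shape, cy, cx, r, r)
      req <- stats::runif(1, spec$nucleus_radius_px[1], spec$nucleus_radius_px[2])
      q <- stats::runif(1, 0.75, 1)          # axis ratio: mildly elliptical
      a <- req / sqrt(q); b <- req * sqrt(q)
      th <- stats::runif(1, 0, pi)
      off <- stats::runif(2, -0.15, 0.15) * r  # nucleus near the cell centre
      nuclei_mask <- nuclei_mask |
        .ellipse_mask(shape, cy + off[1], cx + off[2], a, b, th)
    }
    nuclei_mask <- nuclei_mask & cell_mask

    dgrid_um <- to_microns(compute_distance_map(nuclei_mask),
                           spec$pixel_size_um)$grid
    e <- spec$bin_edges_um
    bin_of <- function(d) ifelse(d < e[1], 1L, ifelse(d < e[2], 2L, 3L))

    particle_mask <- matrix(FALSE, shape[1], shape[2])
    n <- spec$n_particle_pixels
    if (n > 0) {
      cand <- which(cell_mask)
      cand_bin <- bin_of(dgrid_um[cand])
      avail <- tabulate(cand_bin, nbins = 3L)
      w <- spec$radial_weights
      if (any(avail == 0 & w > 0)) {
        warning("radial bin(s) ", paste(which(avail == 0 & w > 0),
                                        collapse = ", "),
                " have no cell pixels; reassigning their weight")
        w[avail == 0] <- 0
        if (sum(w) == 0) stop("no radial bin has available cell pixels")
        w <- w / sum(w)
      }
      want <- as.integer(stats::rmultinom(1, n, w))
      over <- want - avail
      if (any(over > 0 & want > 0)) {
        warning("bin(s) ", paste(which(over > 0), collapse = ", "),
                " have fewer cell pixels than requested; capping")
        want <- pmin(want, avail)
      }
      picked <- integer(0)
      for (b3 in 1:3) {
        if (want[b3] == 0) next
        pool <- cand[cand_bin == b3]
        picked <- c(picked, sample(pool, want[b3], replace = FALSE))
      }
      particle_mask[picked] <- TRUE
      if (spec$dilate_particles) {
        idx <- which(particle_mask, arr.ind = TRUE)
        for (dr in 0:1) for (dc in 0:1) {
          r2 <- pmin(idx[, 1] + dr, shape[1])
          c2 <- pmin(idx[, 2] + dc, shape[2])
          particle_mask[cbind(r2, c2)] <- TRUE
        }
        particle_mask <- particle_mask & cell_mask
      }
    }

    pidx <- which(particle_mask, arr.ind = TRUE)
    distances_um <- dgrid_um[particle_mask]
    # self-consistency: truth distances must equal the exact EDT
    check <- to_microns(compute_distance_map(nuclei_mask),
                        spec$pixel_size_um)$grid[particle_mask]
    stopifnot(max(c(0, abs(distances_um - check))) <= 1e-9)

    render <- function(mask, lev, puncta = FALSE) {
      img <- matrix(lev["bg"], shape[1], shape[2])
      img[mask] <- lev["fg"]
      if (spec$noise_sd > 0)
        img <- img + matrix(stats::rnorm(prod(shape), 0, spec$noise_sd),
                            shape[1], shape[2])
      pmax(img, 0)
    }
    sc <- scene(list(nuclei = render(nuclei_mask, spec$intensities$nuclei),
                     cell = render(cell_mask, spec$intensities$cell),
                     particle = render(particle_mask, spec$intensities$particle)),
                pixel_size_um = spec$pixel_size_um, meta = spec$meta)

    nb <- if (length(distances_um)) bin_of(distances_um) else integer(0)
    true_pct <- if (length(nb)) 100 * tabulate(nb, 3L) / length(nb) else
      rep(NA_real_, 3)
    truth <- structure(list(
      nuclei_mask = nuclei_mask, cell_mask = cell_mask,
      particle_mask = particle_mask,
      particle_pixels = pidx, distances_um = distances_um,
      radial_weights = spec$radial_weights, true_bin_pct = true_pct,
      seed = spec$seed), class = "GroundTruth")
    list(scene = sc, truth = truth)
  })
}

#' Specify a synthetic dry-state micrograph
#'
#' Emulates an electron-micrograph-like field of bright, near-circular,
#' non-overlapping particles on a dark background, with equivalent diameters
#' drawn from a truncated (positive) normal distribution.
#'
#' @param seed RNG seed.
#' @param image_shape `(rows, cols)` in pixels.
#' @param pixel_size_um microns per pixel (default 0.005, i.e. 5 nm/px).
#' @param n_particles particles per field (default 100).
#' @param diameter_um `c(mean, sd)` of the equivalent-diameter distribution
#'   in microns (default 0.099 +/- 0.005, i.e. 99 +/- 5 nm).
#' @param eccentricity_range `(min, max)` ellipse eccentricity (default
#'   `c(0, 0.4)`, mildly aspherical).
#' @param intensities `c(bg, fg)` levels.
#' @param noise_sd additive Gaussian noise SD.
#' @return an object of class `MicrographSpec`.
#' @export
micrograph_spec <- function(seed = 1L, image_shape = c(768L, 768L),
                            pixel_size_um = 0.005, n_particles = 100L,
                            diameter_um = c(mean = 0.099, sd = 0.005),
                            eccentricity_range = c(0, 0.4),
                            intensities = c(bg = 10, fg = 200),
                            noise_sd = 8) {
  if (diameter_um[1] <= 0 || diameter_um[2] < 0)
    stop("diameter mean must be positive and sd non-negative")
  if (any(eccentricity_range < 0) || any(eccentricity_range >= 1) ||
      diff(eccentricity_range) < 0)
    stop("'eccentricity_range' must be non-decreasing within [0, 1)")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be positive")
  if (n_particles < 0) stop("'n_particles' must be >= 0")
  structure(list(seed = as.integer(seed), image_shape = as.integer(image_shape),
                 pixel_size_um = pixel_size_um,
                 n_particles = as.integer(n_particles),
                 diameter_um = diameter_um,
                 eccentricity_range = eccentricity_range,
                 intensities = intensities, noise_sd = noise_sd),
            class = "MicrographSpec")
}

# Ramanujan's second ellipse-perimeter approximation (continuous geometry)
.ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Generate a synthetic micrograph with a per-particle truth table
#'
#' Particles are rendered as filled ellipses with the requested equivalent
#' diameters (truncated-normal, redrawn if non-positive) and eccentricities,
#' placed without overlap by rejection sampling. Truth circularity uses the
#' continuous ellipse geometry (`4*pi*A/P^2` with Ramanujan's perimeter).
#'
#' @param spec a [micrograph_spec()].
#' @return list with `image` (intensity matrix) and `truth`, a `data.frame`
#'   with one row per particle: `id`, `center_row`, `center_col`,
#'   `diameter_um`, `axis_ratio`, `theta`, `circularity`.
#' @export
generate_micrograph <- function(spec) {
  stopifnot(inherits(spec, "MicrographSpec"))
  .with_seed(spec$seed, {
    shape <- spec$image_shape
    img_mask <- matrix(FALSE, shape[1], shape[2])
    rows <- list()
    attempts <- 0L
    placed <- matrix(numeric(0), 0, 3)  # cy, cx, max semi-axis
    while (length(rows) < spec$n_particles) {
      if (attempts >= 1e4)
        stop("micrograph placement failed: placed ", length(rows), " of ",
             spec$n_particles, " particles in 10000 attempts")
      attempts <- attempts + 1L
      d_um <- stats::rnorm(1, spec$diameter_um[1], spec$diameter_um[2])
      if (d_um <= 0) next  # truncation at zero
      d_px <- d_um / spec$pixel_size_um
      ecc <- stats::runif(1, spec$eccentricity_range[1],
                          spec$eccentricity_range[2])
      q <- sqrt(1 - ecc^2)              # axis ratio b/a
      a <- (d_px / 2) / sqrt(q)
      b <- (d_px / 2) * sqrt(q)
      th <- stats::runif(1, 0, pi)
      lo <- a + 3
      if (shape[1] - lo <= lo || shape[2] - lo <= lo)
        stop("micrograph placement failed: particle larger than frame")
      cy <- stats::runif(1, lo, shape[1] - lo)
      cx <- stats::runif(1, lo, shape[2] - lo)
      if (nrow(placed) > 0) {
        dd <- sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2)
        if (any(dd <= placed[, 3] + a + 3)) next
      }
      img_mask <- img_mask | .ellipse_mask(shape, cy, cx, a, b, th)
      placed <- rbind(placed, c(cy, cx, a))
      p_cont <- .ellipse_perimeter(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        id = length(rows) + 1L, center_row = cy, center_col = cx,
        diameter_um = d_um, axis_ratio = q, theta = th,
        circularity = min(4 * pi * (pi * a * b) / p_cont^2, 1))
    }
    img <- matrix(spec$intensities["bg"], shape[1], shape[2])
    img[img_mask] <- spec$intensities["fg"]
    if (spec$noise_sd > 0)
      img <- img + matrix(stats::rnorm(prod(shape), 0, spec$noise_sd),
                          shape[1], shape[2])
    img <- pmax(img, 0)
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(id = integer(), center_row = numeric(),
                 center_col = numeric(), diameter_um = numeric(),
                 axis_ratio = numeric(), theta = numeric(),
                 circularity = numeric())
    list(image = img, truth = truth)
  })
}

#' End-to-end recovery report on a synthetic scene
#'
#' Generates a scene, runs the full segmentation + localization pipeline on
#' the rendered channels (never on the ground-truth masks), and compares the
#' estimated three-bin percentages with the generating truth.
#'
#' @param spec a [scene_spec()].
#' @param config pipeline configuration, a [nanoloc_config()].
#' @return a `data.frame` with columns `bin`, `true_pct`, `estimated_pct`
#'   and `abs_diff_pct`; attributes `n_true`, `n_estimated` and `seed`.
#' @export
recovery_report <- function(spec, config = nanoloc_config()) {
  stopifnot(inherits(spec, "SceneSpec"))
  gen <- generate_scene(spec)
  res <- tryCatch(analyze_scene(gen$scene, config), error = function(e)
    stop("pipeline failed on scene seed ", spec$seed, ": ",
         conditionMessage(e)))
  est <- c(res$summary$perinuclear_pct, res$summary$intermediate_pct,
           res$summary$peripheral_pct)
  true <- gen$truth$true_bin_pct
  out <- data.frame(bin = c("perinuclear", "intermediate", "peripheral"),
                    true_pct = true, estimated_pct = est,
                    abs_diff_pct = abs(est - true))
  attr(out, "n_true") <- length(gen$truth$distances_um)
  attr(out, "n_estimated") <- res$summary$n_pixels
  attr(out, "seed") <- spec$seed
  out
}
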