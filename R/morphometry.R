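#' @title Dry-state particle morphometry
#' @description ImageJ-style size and shape population analysis of
#'   micrograph images: equivalent diameter `2*sqrt(A/pi)` and circularity
#'   `4*pi*A/P^2` with a Crofton 4-direction perimeter estimate, capped at 1.
#' @name morphometry
NULL

#' Crofton 4-direction perimeter of a binary object
#'
#' Estimates the boundary length of a binary region from its 2x2 pixel
#' configuration histogram using the Crofton formula with four test-line
#' directions (horizontal, vertical and the two diagonals). This is the
#' estimator family behind ImageJ-style circularity; a naive
#' boundary-pixel count overestimates perimeters of digitized smooth shapes,
#' which would bias circularity low.
#'
#' @param mask logical or 0/1 matrix, TRUE/1 inside the object.
#' @return perimeter estimate in pixel units (0 for an empty mask).
#' @export
crofton_perimeter <- function(mask) {
  if (is.logical(mask)) mask <- mask * 1
  if (!is.matrix(mask)) stop("'mask' must be a matrix")
  # zero-pad so every 2x2 window touching the object is counted
  p <- matrix(0, nrow(mask) + 2L, ncol(mask) + 2L)
  p[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- (mask > 0) * 1
  nr <- nrow(p); nc <- ncol(p)
  # configuration code of the 2x2 window ending at (i, j):
  # 1*p(i,j) + 4*p(i,j-1) + 2*p(i-1,j) + 8*p(i-1,j-1)
  A <- p
  L <- cbind(0, p[, -nc])
  U <- rbind(0, p[-nr, ])
  UL <- rbind(0, cbind(0, p[-nr, -nc]))
  code <- A + 4 * L + 2 * U + 8 * UL
  h <- tabulate(code + 1L, nbins = 16L)
  s2 <- sqrt(2)
  coefs <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2), 0,
             pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2), pi / 4, pi / 2,
             pi / (4 * s2), pi / (4 * s2), pi / 4, pi / 2, 0, 0)
  sum(coefs * h)
}

#' Circularity of a segmented object
#'
#' `4*pi*Area/Perimeter^2`: 1 for a perfect circle, smaller for elongated or
#' rough shapes. Values slightly above 1 arising from perimeter
#' digitization are capped at 1, following the ImageJ convention.
#'
#' @param area_px object area in pixels (> 0); vectorized.
#' @param perimeter_px object perimeter in pixel units (> 0); vectorized.
#' @return circularity in (0, 1].
#' @export
circularity <- function(area_px, perimeter_px) {
  if (any(area_px <= 0) || any(perimeter_px <= 0))
    stop("'area_px' and 'perimeter_px' must be positive")
  pmin(4 * pi * area_px / perimeter_px^2, 1)
}

#' Detect and measure particles in a micrograph
#'
#' Segments bright particles on a dark background (Gaussian smoothing +
#' Otsu, hole filling, 4-connected labelling), excludes objects touching the
#' image border (partial particles bias the size distribution) and objects
#' below `min_area_px`, and measures each remaining particle.
#'
#' @param micrograph single-channel numeric matrix of intensities.
#' @param pixel_size_um microns per pixel (> 0).
#' @param min_area_px minimum particle area in pixels (default 10).
#' @param smoothing_sigma Gaussian pre-smoothing sigma (default 1).
#' @return a `data.frame` with one row per particle: `label`, `area_px`,
#'   `perimeter_px` (Crofton 4-direction), `equivalent_diameter_um`
#'   (`2*sqrt(A/pi)*pixel_size_um`) and `circularity` (capped at 1). A blank
#'   image yields zero rows.
#' @export
detect_particles <- function(micrograph, pixel_size_um, min_area_px = 10,
                             smoothing_sigma = 1) {
  if (!is.matrix(micrograph) || !is.numeric(micrograph))
    stop("'micrograph' must be a numeric matrix")
  if (pixel_size_um <= 0) stop("'pixel_size_um' must be positive")
  empty <- data.frame(label = integer(), area_px = numeric(),
                      perimeter_px = numeric(),
                      equivalent_diameter_um = numeric(),
                      circularity = numeric())
  if (!.has_contrast(micrograph)) return(empty)
  sm <- .gaussian_smooth(micrograph, smoothing_sigma)
  bw <- sm > .otsu_threshold(sm)
  bw <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  if (max(lab) == 0) return(empty)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  keep <- setdiff(seq_len(max(lab)), border)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  keep <- keep[areas[keep] >= min_area_px]
  if (length(keep) == 0L) return(empty)
  rows <- lapply(seq_along(keep), function(i) {
    k <- keep[i]
    idx <- which(lab == k, arr.ind = TRUE)
    rr <- range(idx[, 1]); cc <- range(idx[, 2])
    sub <- lab[rr[1]:rr[2], cc[1]:cc[2], drop = FALSE] == k
    a <- areas[k]
    p <- crofton_perimeter(sub)
    data.frame(label = i, area_px = a, perimeter_px = p,
               equivalent_diameter_um = 2 * sqrt(a / pi) * pixel_size_um,
               circularity = circularity(a, p))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a particle population
#'
#' Pools per-particle measurements (typically across several micrographs of
#' the same formulation) and reports count, mean, sample SD and coefficient
#' of variation for equivalent diameter and circularity.
#'
#' @param shapes a `data.frame` as returned by [detect_particles()], or a
#'   row-bound concatenation of several.
#' @return a `PopulationStats` list: `n`, and `mean`, `sd`, `cv` for
#'   `diameter` (um) and `circularity`.
#' @export
summarize_population <- function(shapes) {
  if (!is.data.frame(shapes) || nrow(shapes) == 0L)
    stop("'shapes' must be a non-empty data.frame of particle measurements")
  req <- c("equivalent_diameter_um", "circularity")
  if (!all(req %in% names(shapes)))
    stop("'shapes' must have columns: ", paste(req, collapse = ", "))
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  stat <- function(x) {
    m <- mean(x); s <- sd0(x)
    list(mean = m, sd = s, cv = if (m > 0) s / m else NA_real_)
  }
  structure(list(n = nrow(shapes),
                 diameter = stat(shapes$equivalent_diameter_um),
                 circularity = stat(shapes$circularity)),
            class = "PopulationStats")
}

#' @export
print.PopulationStats <- function(x, ...) {
  cat(sprintf(
    "PopulationStats (n = %d): diameter %.4g +/- %.3g um, circularity %.3f +/- %.3f\n",
    x$n, x$diameter$mean, x$diameter$sd,
    x$circularity$mean, x$circularity$sd))
  invisible(x)
}
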