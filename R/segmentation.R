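#' @title Channel segmentation for nanoparticle localization
#' @description Thresholding and mask clean-up for the nuclei, cell and
#'   particle channels of a [scene()]. All operations are deterministic:
#'   identical scene and parameters give bit-identical masks.
#' @name segmentation
NULL

# TRUE when the grid has any dynamic range at all
.has_contrast <- function(x) {
  r <- range(x)
  is.finite(r[2] - r[1]) && (r[2] - r[1]) > 0
}

# Otsu threshold in the original intensity units (EBImage::otsu works on 0-1)
.otsu_threshold <- function(x) {
  r <- range(x)
  norm <- (x - r[1]) / (r[2] - r[1])
  t01 <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1), levels = 256)
  r[1] + t01 * (r[2] - r[1])
}

.gaussian_smooth <- function(x, sigma) {
  if (sigma <= 0) return(x)
  EBImage::imageData(EBImage::gblur(EBImage::Image(x), sigma = sigma))
}

.disc_brush <- function(radius_px) {
  EBImage::makeBrush(2L * as.integer(radius_px) + 1L, shape = "disc")
}

#' Segment nuclei from the DAPI channel
#'
#' Gaussian pre-smoothing, global Otsu threshold, morphological opening,
#' hole filling, connected-component labelling (4-connectivity) and removal
#' of objects below a minimum area. Touching nuclei are not split: the
#' downstream distance-to-nearest-nucleus analysis is insensitive to merged
#' labels.
#'
#' @param scene a [scene()] with a `"nuclei"` channel.
#' @param min_area_px minimum object area in pixels (default 50).
#' @param smoothing_sigma Gaussian pre-smoothing sigma in pixels (default 1).
#' @param opening_radius_px disc radius of the morphological opening
#'   (default 2; 0 disables).
#' @return a [label_mask()] of nuclear objects. A channel with zero dynamic
#'   range raises a "no-contrast" error rather than returning an empty mask.
#' @export
segment_nuclei <- function(scene, min_area_px = 50, smoothing_sigma = 1,
                           opening_radius_px = 2) {
  stopifnot(inherits(scene, "Scene"))
  ch <- scene$channels$nuclei
  if (is.null(ch)) stop("scene has no 'nuclei' channel")
  if (!.has_contrast(ch))
    stop("no-contrast nuclei channel: zero dynamic range, cannot segment")
  sm <- .gaussian_smooth(ch, smoothing_sigma)
  thr <- .otsu_threshold(sm)
  bw <- sm > thr
  if (opening_radius_px > 0)
    bw <- EBImage::imageData(
      EBImage::opening(EBImage::Image(bw * 1), .disc_brush(opening_radius_px))) > 0
  bw <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  if (min_area_px > 0 && max(lab) > 0) {
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(areas < min_area_px)
    if (length(drop)) lab[lab %in% drop] <- 0
  }
  label_mask(lab)
}

#' Segment the cell area from the cytoskeleton channel
#'
#' Smoothing, Otsu threshold, morphological closing and hole filling produce
#' a single boolean cell-area mask (no per-cell instances). When `nuclei` is
#' supplied the nuclear pixels are unioned in, so that every nucleus lies
#' inside the cell area. A channel with zero dynamic range falls back to a
#' full-frame mask with a warning, making intracellular gating a no-op.
#'
#' @param scene a [scene()] with a `"cell"` channel.
#' @param closing_radius_px disc radius of the morphological closing used to
#'   bridge gaps in cytoskeletal staining (default 5).
#' @param smoothing_sigma Gaussian pre-smoothing sigma (default 1).
#' @param nuclei optional [label_mask()] or [binary_mask()] of nuclei to
#'   reconcile into the cell mask.
#' @return a [binary_mask()] with role `"cell"`.
#' @export
segment_cells <- function(scene, closing_radius_px = 5, smoothing_sigma = 1,
                          nuclei = NULL) {
  stopifnot(inherits(scene, "Scene"))
  ch <- scene$channels$cell
  if (is.null(ch)) stop("scene has no 'cell' channel")
  if (!.has_contrast(ch)) {
    warning("no-contrast cell channel: falling back to full-frame cell mask")
    bw <- matrix(TRUE, nrow(ch), ncol(ch))
    thr <- NA_real_
    method <- "full-frame-fallback"
  } else {
    sm <- .gaussian_smooth(ch, smoothing_sigma)
    thr <- .otsu_threshold(sm)
    bw <- sm > thr
    if (closing_radius_px > 0)
      bw <- EBImage::imageData(
        EBImage::closing(EBImage::Image(bw * 1), .disc_brush(closing_radius_px))) > 0
    bw <- EBImage::imageData(EBImage::fillHull(EBImage::Image(bw * 1))) > 0
    method <- "otsu+closing+fill"
  }
  if (!is.null(nuclei)) bw <- bw | .mask_grid(nuclei)
  binary_mask(bw, role = "cell", threshold = thr, method = method)
}

#' Segment particle-positive pixels
#'
#' Particle puncta are pixel-scale, so the channel is thresholded without
#' smoothing. The primary threshold is Otsu's; because Otsu misbehaves on the
#' near-unimodal histograms of sparse puncta, the threshold falls back to a
#' high intensity percentile whenever the Otsu foreground exceeds
#' `max_otsu_foreground` of the frame. A channel with zero dynamic range
#' yields an empty mask: untreated control images legitimately contain no
#' particle signal.
#'
#' @param scene a [scene()] with a `"particle"` channel.
#' @param fallback_quantile percentile used when Otsu fails (default 0.995).
#' @param max_otsu_foreground maximum tolerated Otsu foreground fraction
#'   (default 0.20).
#' @return a [binary_mask()] with role `"particle"` (binary, not
#'   intensity-weighted).
#' @export
segment_particles <- function(scene, fallback_quantile = 0.995,
                              max_otsu_foreground = 0.20) {
  stopifnot(inherits(scene, "Scene"))
  ch <- scene$channels$particle
  if (is.null(ch)) stop("scene has no 'particle' channel")
  if (!.has_contrast(ch))
    return(binary_mask(matrix(FALSE, nrow(ch), ncol(ch)), role = "particle",
                       method = "no-contrast-empty"))
  thr <- .otsu_threshold(ch)
  bw <- ch > thr
  method <- "otsu"
  if (mean(bw) > max_otsu_foreground) {
    thr <- stats::quantile(ch, fallback_quantile, names = FALSE)
    bw <- ch > thr
    method <- sprintf("percentile-%.4g", fallback_quantile)
  }
  binary_mask(bw, role = "particle", threshold = thr, method = method)
}

#' Remove artifacts and extracellular signal from a particle mask
#'
#' Artifact removal keeps the analysis to intracellular particle signal:
#' particle pixels outside the cell mask are discarded, and remaining
#' connected components (4-connectivity) smaller than `min_component_px` are
#' treated as noise specks and removed. The operation is idempotent and its
#' output is always a subset of `particles & cells`.
#'
#' @param particles particle [binary_mask()] (or logical matrix).
#' @param cells cell-area [binary_mask()] (or logical matrix) of the same
#'   dimensions.
#' @param min_component_px minimum connected-component area kept (default 2).
#' @return a cleaned [binary_mask()] with role `"particle"`.
#' @export
clean_particle_mask <- function(particles, cells, min_component_px = 2) {
  p <- .mask_grid(particles)
  cg <- .mask_grid(cells)
  if (!identical(dim(p), dim(cg)))
    stop("particle and cell masks must share dimensions")
  p <- p & cg
  if (min_component_px > 1 && any(p)) {
    lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(p * 1)))
    areas <- tabulate(lab[lab > 0], nbins = max(lab))
    drop <- which(areas < min_component_px)
    if (length(drop)) p[lab %in% drop] <- FALSE
  }
  binary_mask(p, role = "particle", method = "cleaned")
}
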