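#' @title Distance-to-nearest-nucleus localization
#' @description The core quantification: an exact Euclidean distance map
#'   from the segmented nuclei, micron scaling, per-particle-pixel distance
#'   extraction, radial histograms and the three-bin spatial summary
#'   (perinuclear 0-5 um, intermediate 5-10 um, peripheral >10 um).
#' @name localization
NULL

#' Exact Euclidean distance map to the nearest nucleus
#'
#' For every pixel, the straight-line distance (in pixel units) to the
#' nearest nuclear pixel; exactly 0 on nuclei. Distances are measured to the
#' nuclear region, not its centroid, so pixels inside a nucleus are
#' perinuclear by definition.
#'
#' @param nuclei a [label_mask()], [binary_mask()] or matrix; nonzero/TRUE
#'   pixels are nuclear.
#' @return a `DistanceMap` (fields `grid`, `units = "px"`). An empty nuclei
#'   mask raises a "no-nuclei" error so the image can be excluded upstream.
#' @export
compute_distance_map <- function(nuclei) {
  fg <- .mask_grid(nuclei)
  if (!any(fg))
    stop("no-nuclei: the nuclei mask is empty; image cannot be analyzed")
  # distmap() gives each foreground pixel its distance to the nearest
  # background pixel, so invert: background-of-nuclei gets distance-to-nuclei
  d <- EBImage::imageData(
    EBImage::distmap(EBImage::Image((!fg) * 1), metric = "euclidean"))
  structure(list(grid = d, units = "px"), class = "DistanceMap")
}

#' @export
print.DistanceMap <- function(x, ...) {
  cat(sprintf("DistanceMap %dx%d [%s], max %.3f\n",
              nrow(x$grid), ncol(x$grid), x$units, max(x$grid)))
  invisible(x)
}

#' Convert a pixel-unit distance map to microns
#'
#' @param dmap a `DistanceMap` in pixel units.
#' @param pixel_size_um microns per pixel; the default 0.15537 is the
#'   package's confocal calibration, used whenever image metadata omits a
#'   scale.
#' @return a `DistanceMap` with `units = "um"`.
#' @export
to_microns <- function(dmap, pixel_size_um = 0.15537) {
  stopifnot(inherits(dmap, "DistanceMap"))
  if (dmap$units != "px") stop("distance map is not in pixel units")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  structure(list(grid = dmap$grid * pixel_size_um, units = "um"),
            class = "DistanceMap")
}

#' Distances of particle-positive pixels to the nearest nucleus
#'
#' Binary per-pixel counting: each particle-positive pixel contributes one
#' distance regardless of its intensity.
#'
#' @param dmap_um a `DistanceMap` in microns.
#' @param particles particle [binary_mask()] (or logical matrix) of matching
#'   dimensions.
#' @return numeric vector of distances in microns, one per particle pixel
#'   (possibly empty).
#' @export
particle_distances <- function(dmap_um, particles) {
  stopifnot(inherits(dmap_um, "DistanceMap"))
  if (dmap_um$units != "um")
    stop("distance map must be in microns; call to_microns() first")
  p <- .mask_grid(particles)
  if (!identical(dim(p), dim(dmap_um$grid)))
    stop("distance map and particle mask must share dimensions")
  as.numeric(dmap_um$grid[p])
}

#' Radial distance histogram of particle signal
#'
#' Fixed-width half-open bins `[0,w), [w,2w), ...` up to `max_edge_um`, plus
#' one open-ended final bin `[max_edge_um, Inf)`. Percentages are normalized
#' to 100 over all particle pixels.
#'
#' @param distances numeric vector of per-pixel distances in microns.
#' @param bin_width_um bin width in microns (default 0.5).
#' @param max_edge_um last finite bin edge (default 30).
#' @return a `RadialHistogram` with fields `bin_edges_um` (finite edges),
#'   `counts` (one per bin including the open-ended last), `percent` and `n`.
#'   Empty input gives an all-zero histogram with `n = 0`.
#' @export
radial_histogram <- function(distances, bin_width_um = 0.5, max_edge_um = 30) {
  if (bin_width_um <= 0) stop("'bin_width_um' must be positive")
  if (max_edge_um <= 0) stop("'max_edge_um' must be positive")
  if (any(distances < 0)) stop("distances must be non-negative")
  edges <- seq(0, max_edge_um, by = bin_width_um)
  if (edges[length(edges)] < max_edge_um) edges <- c(edges, max_edge_um)
  breaks <- c(edges, Inf)
  n <- length(distances)
  counts <- if (n == 0L) integer(length(breaks) - 1L) else
    as.integer(table(cut(distances, breaks = breaks, right = FALSE,
                         include.lowest = FALSE)))
  percent <- if (n > 0L) 100 * counts / n else counts * 0
  structure(list(bin_edges_um = edges, counts = counts, percent = percent,
                 n = n),
            class = "RadialHistogram")
}

#' @export
print.RadialHistogram <- function(x, ...) {
  cat(sprintf("RadialHistogram: %d bins, n = %d particle px\n",
              length(x$counts), x$n))
  invisible(x)
}

#' Three-bin spatial summary of particle distances
#'
#' Classifies distances into half-open bins `[0, e1)`, `[e1, e2)` and
#' `[e2, Inf)` microns -- by default the perinuclear (0-5 um), intermediate
#' (5-10 um) and peripheral (>10 um) regions -- and reports the percentage
#' of intracellular particle pixels in each.
#'
#' @param distances numeric vector of per-pixel distances in microns.
#' @param edges two strictly increasing positive bin edges in microns
#'   (default `c(5, 10)`).
#' @param meta condition metadata carried into aggregation (`image_id`,
#'   `dosage_label`, `timepoint_h`).
#' @return a `BinSummary` with fields `perinuclear_pct`, `intermediate_pct`,
#'   `peripheral_pct`, `n_pixels` and `meta`. With no distances the
#'   percentages are `NA` and the summary is flagged `empty` (excluded from
#'   aggregation).
#' @export
bin_summary <- function(distances, edges = c(5, 10), meta = list()) {
  if (length(edges) != 2L || any(edges <= 0) || diff(edges) <= 0)
    stop("'edges' must be two strictly increasing positive values")
  if (any(distances < 0)) stop("distances must be non-negative")
  n <- length(distances)
  if (n == 0L) {
    return(structure(list(perinuclear_pct = NA_real_,
                          intermediate_pct = NA_real_,
                          peripheral_pct = NA_real_,
                          n_pixels = 0L, empty = TRUE, meta = meta),
                     class = "BinSummary"))
  }
  counts <- c(sum(distances < edges[1]),
              sum(distances >= edges[1] & distances < edges[2]),
              sum(distances >= edges[2]))
  pct <- 100 * counts / n
  structure(list(perinuclear_pct = pct[1], intermediate_pct = pct[2],
                 peripheral_pct = pct[3], n_pixels = as.integer(n),
                 empty = FALSE, meta = meta),
            class = "BinSummary")
}

#' @export
print.BinSummary <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("BinSummary: empty (no intracellular particle pixels)\n")
  } else {
    cat(sprintf(
      "BinSummary (n = %d px): perinuclear %.1f%%, intermediate %.1f%%, peripheral %.1f%%\n",
      x$n_pixels, x$perinuclear_pct, x$intermediate_pct, x$peripheral_pct))
  }
  invisible(x)
}

#' Aggregate per-image bin summaries by experimental condition
#'
#' Groups per-image summaries by `(dosage_label, timepoint_h)` and reports
#' the mean and sample SD of each bin percentage plus the number of images.
#' Per-image normalization precedes averaging (each image is one biological
#' replicate with equal weight), so large images do not dominate. Empty
#' summaries are dropped with a warning; a group left with no images is
#' omitted.
#'
#' @param summaries list of `BinSummary` objects.
#' @return a `data.frame` (the condition table) with one row per condition:
#'   `dosage_label`, `timepoint_h`, `n_images`, and `<bin>_mean`/`<bin>_sd`
#'   for the three bins. Rows are sorted by dosage label then timepoint for
#'   reproducible output.
#' @export
aggregate_conditions <- function(summaries) {
  stopifnot(is.list(summaries),
            all(vapply(summaries, inherits, logical(1), "BinSummary")))
  empty <- vapply(summaries, function(s) isTRUE(s$empty), logical(1))
  if (any(empty)) {
    warning(sum(empty), " empty summar",
            if (sum(empty) == 1L) "y" else "ies",
            " excluded from aggregation")
    summaries <- summaries[!empty]
  }
  if (length(summaries) == 0L)
    return(data.frame(dosage_label = character(), timepoint_h = numeric(),
                      n_images = integer(),
                      perinuclear_mean = numeric(), perinuclear_sd = numeric(),
                      intermediate_mean = numeric(), intermediate_sd = numeric(),
                      peripheral_mean = numeric(), peripheral_sd = numeric()))
  df <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(
      dosage_label = as.character(if (is.null(s$meta$dosage_label)) NA else s$meta$dosage_label),
      timepoint_h = as.numeric(if (is.null(s$meta$timepoint_h)) NA else s$meta$timepoint_h),
      perinuclear = s$perinuclear_pct, intermediate = s$intermediate_pct,
      peripheral = s$peripheral_pct, stringsAsFactors = FALSE)
  }))
  key <- interaction(df$dosage_label, df$timepoint_h, drop = TRUE)
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  out <- do.call(rbind, lapply(split(df, key), function(g) {
    data.frame(
      dosage_label = g$dosage_label[1], timepoint_h = g$timepoint_h[1],
      n_images = nrow(g),
      perinuclear_mean = mean(g$perinuclear), perinuclear_sd = sd0(g$perinuclear),
      intermediate_mean = mean(g$intermediate), intermediate_sd = sd0(g$intermediate),
      peripheral_mean = mean(g$peripheral), peripheral_sd = sd0(g$peripheral),
      stringsAsFactors = FALSE)
  }))
  out <- out[order(out$dosage_label, out$timepoint_h), , drop = FALSE]
  rownames(out) <- NULL
  out
}
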