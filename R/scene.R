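#' Construct a multichannel fluorescence scene
#'
#' A `Scene` bundles the 2D intensity grids of a single confocal field of
#' view together with its pixel scale and condition metadata. Channels are
#' identified by role: `"nuclei"` (DAPI), `"cell"` (phalloidin, used to
#' delineate the cell area) and `"particle"` (labelled nanoparticles).
#'
#' @param channels named list of numeric matrices; names are channel roles
#'   (any subset of `"nuclei"`, `"cell"`, `"particle"`). All grids must share
#'   identical dimensions and contain finite, non-negative intensities.
#' @param pixel_size_um physical size of one pixel in microns (scalar > 0).
#'   The default is the confocal calibration used throughout the package,
#'   1 pixel = 0.15537 um.
#' @param meta list of condition labels; recognised fields are `image_id`,
#'   `dosage_label` and `timepoint_h`. Free-form extra fields are kept.
#' @return an object of class `Scene`.
#' @examples
#' sc <- scene(list(nuclei = matrix(0, 8, 8), particle = matrix(0, 8, 8)))
#' dim(sc)
#' @export
scene <- function(channels, pixel_size_um = 0.15537, meta = list()) {
  if (!is.list(channels) || length(channels) == 0L || is.null(names(channels)))
    stop("'channels' must be a non-empty named list of matrices")
  bad <- setdiff(names(channels), c("nuclei", "cell", "particle"))
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1))))
    stop("every channel must be a matrix")
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L)
    stop("all channel grids must share identical dimensions")
  for (nm in names(channels)) {
    g <- channels[[nm]]
    if (!is.numeric(g) || any(!is.finite(g)) || any(g < 0))
      stop("channel '", nm, "' must contain finite, non-negative intensities")
    storage.mode(channels[[nm]]) <- "double"
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("'pixel_size_um' must be a single positive number")
  structure(
    list(channels = channels, pixel_size_um = pixel_size_um, meta = meta),
    class = "Scene"
  )
}

#' @export
dim.Scene <- function(x) dim(x$channels[[1L]])

#' @export
print.Scene <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("Scene %dx%d px (%.5f um/px), channels: %s\n",
              d[1], d[2], x$pixel_size_um,
              paste(names(x$channels), collapse = ", ")))
  if (length(x$meta))
    cat("  meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Construct a binary mask
#'
#' @param grid logical matrix (TRUE = inside the mask).
#' @param role mask role, one of `"nuclei"`, `"cell"`, `"particle"`.
#' @param threshold optional intensity threshold that produced the mask, kept
#'   for reporting.
#' @param method optional character tag describing how the mask was produced.
#' @return object of class `BinaryMask` with fields `grid`, `role`,
#'   `threshold` and `method`.
#' @export
binary_mask <- function(grid, role = c("particle", "nuclei", "cell"),
                        threshold = NA_real_, method = NA_character_) {
  role <- match.arg(role)
  if (is.numeric(grid)) grid <- grid > 0
  if (!is.logical(grid) || is.null(dim(grid)))
    stop("'grid' must be a logical matrix")
  structure(list(grid = grid, role = role,
                 threshold = threshold, method = method),
            class = "BinaryMask")
}

#' @export
print.BinaryMask <- function(x, ...) {
  cat(sprintf("BinaryMask [%s] %dx%d, %d positive px\n", x$role,
              nrow(x$grid), ncol(x$grid), sum(x$grid)))
  invisible(x)
}

#' Construct a label mask of connected objects
#'
#' Labels are relabelled to be contiguous `1..n_objects`; 0 is background.
#'
#' @param grid integer matrix of non-negative labels.
#' @return object of class `LabelMask` with fields `grid` and `n_objects`.
#' @export
label_mask <- function(grid) {
  if (!is.numeric(grid) || is.null(dim(grid)) || any(grid < 0))
    stop("'grid' must be a matrix of non-negative integers")
  labs <- sort(unique(grid[grid > 0]))
  out <- matrix(0L, nrow(grid), ncol(grid))
  for (k in seq_along(labs)) out[grid == labs[k]] <- k
  structure(list(grid = out, n_objects = length(labs)), class = "LabelMask")
}

#' @export
print.LabelMask <- function(x, ...) {
  cat(sprintf("LabelMask %dx%d, %d object(s)\n",
              nrow(x$grid), ncol(x$grid), x$n_objects))
  invisible(x)
}

# Coerce Scene/BinaryMask/LabelMask arguments to a plain grid
.mask_grid <- function(x) {
  if (inherits(x, "BinaryMask")) return(x$grid)
  if (inherits(x, "LabelMask")) return(x$grid > 0)
  if (is.matrix(x)) return(x > 0)
  stop("expected a BinaryMask, LabelMask or matrix")
}

#' Read a single-channel image file
#'
#' Reads PNG or TIFF (by extension); multi-sample images are collapsed to
#' their first plane. Values are returned as stored (PNG is scaled to 0-1 by
#' the reader).
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @return numeric matrix of intensities.
#' @export
read_channel <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image extension: ", ext))
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img
}

#' Read a scene from per-role image files
#'
#' @param paths named character vector or list mapping channel roles to file
#'   paths (names among `"nuclei"`, `"cell"`, `"particle"`).
#' @param pixel_size_um microns per pixel; defaults to 0.15537.
#' @param meta condition metadata list (see [scene()]).
#' @return a `Scene`.
#' @export
read_scene <- function(paths, pixel_size_um = 0.15537, meta = list()) {
  channels <- lapply(paths, read_channel)
  scene(channels, pixel_size_um = pixel_size_um, meta = meta)
}

#' Write a mask or intensity grid as an image file
#'
#' Binary and label masks are rescaled to the 0-1 range expected by the PNG
#' and TIFF writers (labels share one linear ramp); intensity grids are
#' written relative to `max_intensity`.
#'
#' @param x a `BinaryMask`, `LabelMask`, logical or numeric matrix.
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @param max_intensity intensity mapped to white for numeric grids.
#' @return `path`, invisibly.
#' @export
write_mask <- function(x, path, max_intensity = 255) {
  g <- if (inherits(x, c("BinaryMask", "LabelMask"))) x$grid else x
  g <- if (is.logical(g)) g * 1 else g
  mx <- if (all(g %in% c(0, 1))) 1 else if (max(g) > 0) max(g) else 1
  if (!all(g %in% c(0, 1)) && max(g) <= max_intensity &&
      !inherits(x, "LabelMask")) mx <- max_intensity
  g <- pmin(pmax(g / mx, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png  = png::writePNG(g, path),
    tif  = ,
    tiff = tiff::writeTIFF(g, path, bits.per.sample = 16L),
    stop("unsupported image extension: ", ext))
  invisible(path)
}
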