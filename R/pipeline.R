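#' @title End-to-end pipeline and deterministic CSV export
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Collects every tunable parameter of the segmentation and localization
#' stages with the package defaults.
#'
#' @param smoothing_sigma Gaussian pre-smoothing sigma in px for the nuclei
#'   and cell channels (the particle channel is never smoothed).
#' @param opening_radius_px opening disc radius for nuclei.
#' @param min_nucleus_area_px minimum nucleus area.
#' @param closing_radius_px closing disc radius for the cell mask.
#' @param min_component_px minimum particle component area kept by cleaning.
#' @param fallback_quantile particle-threshold percentile fallback.
#' @param max_otsu_foreground Otsu foreground fraction above which the
#'   particle threshold falls back to the percentile.
#' @param bin_edges_um the two spatial bin edges in microns.
#' @param bin_width_um radial histogram bin width.
#' @param max_edge_um radial histogram last finite edge.
#' @param pixel_size_um microns per pixel; `NULL` uses each scene's own
#'   value.
#' @return a list of class `nanoloc_config`.
#' @export
nanoloc_config <- function(smoothing_sigma = 1, opening_radius_px = 2,
                           min_nucleus_area_px = 50, closing_radius_px = 5,
                           min_component_px = 2, fallback_quantile = 0.995,
                           max_otsu_foreground = 0.20,
                           bin_edges_um = c(5, 10), bin_width_um = 0.5,
                           max_edge_um = 30, pixel_size_um = NULL) {
  structure(list(smoothing_sigma = smoothing_sigma,
                 opening_radius_px = opening_radius_px,
                 min_nucleus_area_px = min_nucleus_area_px,
                 closing_radius_px = closing_radius_px,
                 min_component_px = min_component_px,
                 fallback_quantile = fallback_quantile,
                 max_otsu_foreground = max_otsu_foreground,
                 bin_edges_um = bin_edges_um, bin_width_um = bin_width_um,
                 max_edge_um = max_edge_um, pixel_size_um = pixel_size_um),
            class = "nanoloc_config")
}

#' Analyze one scene end to end
#'
#' Runs nuclear, cell and particle segmentation, cleans the particle mask to
#' intracellular signal, computes the exact Euclidean distance map in
#' microns, extracts per-particle-pixel distances and summarizes them into
#' the three spatial bins.
#'
#' @param scene a [scene()] with all three channels.
#' @param config a [nanoloc_config()].
#' @return list with `nuclei` (LabelMask), `cells`, `particles_raw`,
#'   `particles` (cleaned BinaryMasks), `dmap_um`, `distances` (data.frame
#'   `pixel_row`, `pixel_col`, `distance_um`), `histogram`
#'   (RadialHistogram) and `summary` (BinSummary carrying the scene's
#'   metadata).
#' @export
analyze_scene <- function(scene, config = nanoloc_config()) {
  stopifnot(inherits(scene, "Scene"), inherits(config, "nanoloc_config"))
  px <- if (is.null(config$pixel_size_um)) scene$pixel_size_um else
    config$pixel_size_um
  nuc <- segment_nuclei(scene, min_area_px = config$min_nucleus_area_px,
                        smoothing_sigma = config$smoothing_sigma,
                        opening_radius_px = config$opening_radius_px)
  cells <- segment_cells(scene, closing_radius_px = config$closing_radius_px,
                         smoothing_sigma = config$smoothing_sigma,
                         nuclei = nuc)
  praw <- segment_particles(scene,
                            fallback_quantile = config$fallback_quantile,
                            max_otsu_foreground = config$max_otsu_foreground)
  pcl <- clean_particle_mask(praw, cells,
                             min_component_px = config$min_component_px)
  dmap_um <- to_microns(compute_distance_map(nuc), px)
  d <- particle_distances(dmap_um, pcl)
  idx <- which(pcl$grid, arr.ind = TRUE)
  distances <- data.frame(pixel_row = as.integer(idx[, 1]),
                          pixel_col = as.integer(idx[, 2]),
                          distance_um = as.numeric(dmap_um$grid[pcl$grid]))
  distances <- distances[order(distances$pixel_row, distances$pixel_col), ,
                         drop = FALSE]
  rownames(distances) <- NULL
  list(nuclei = nuc, cells = cells, particles_raw = praw, particles = pcl,
       dmap_um = dmap_um, distances = distances,
       histogram = radial_histogram(d, config$bin_width_um,
                                    config$max_edge_um),
       summary = bin_summary(d, edges = config$bin_edges_um,
                             meta = scene$meta))
}

# Deterministic CSV writer: fixed locale-independent formatting and eol
.write_csv <- function(df, path) {
  utils::write.csv(format(df, trim = TRUE, digits = 15, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Export a scene analysis as CSV files
#'
#' Writes `<image_id>_distances.csv` (one row per intracellular particle
#' pixel), `<image_id>_histogram.csv` and `<image_id>_summary.csv` into
#' `out_dir`. Output is byte-deterministic: re-running on identical input
#' reproduces identical files.
#'
#' @param result the list returned by [analyze_scene()].
#' @param out_dir output directory (created if absent).
#' @param image_id identifier used in file names; defaults to the scene
#'   metadata carried by the summary, or `"image"`.
#' @return character vector of the files written, invisibly.
#' @export
export_scene_analysis <- function(result, out_dir, image_id = NULL) {
  if (is.null(image_id))
    image_id <- if (!is.null(result$summary$meta$image_id))
      result$summary$meta$image_id else "image"
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(out_dir, paste0(image_id, "_distances.csv"))
  dd <- result$distances
  dd$image_id <- image_id
  .write_csv(dd[c("image_id", "pixel_row", "pixel_col", "distance_um")], f1)
  h <- result$histogram
  f2 <- file.path(out_dir, paste0(image_id, "_histogram.csv"))
  .write_csv(data.frame(bin_start_um = c(h$bin_edges_um),
                        bin_end_um = c(h$bin_edges_um[-1], Inf),
                        count = h$counts, percent = h$percent), f2)
  s <- result$summary
  f3 <- file.path(out_dir, paste0(image_id, "_summary.csv"))
  .write_csv(data.frame(image_id = image_id,
                        n_pixels = s$n_pixels,
                        perinuclear_pct = s$perinuclear_pct,
                        intermediate_pct = s$intermediate_pct,
                        peripheral_pct = s$peripheral_pct), f3)
  invisible(c(f1, f2, f3))
}

#' Write a condition table as CSV
#'
#' @param table the data.frame returned by [aggregate_conditions()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_condition_table <- function(table, path) {
  .write_csv(table, path)
}
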