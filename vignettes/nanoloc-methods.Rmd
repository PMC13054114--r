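---
title: "Quantifying intracellular nanoparticle localization with nanoloc"
author: "nanoloc authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intracellular nanoparticle localization with nanoloc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoloc)
```

## The question the pipeline answers

When cells are dosed with fluorescently labelled nanoparticles, *where* the
particles end up matters as much as *how many* get in: carriers that
accumulate near the nucleus have a shorter diffusion path for their
nucleic-acid payload and sit in the endosomal population most likely to be
acidified, so perinuclear accumulation is a mechanistically meaningful
readout. `nanoloc` turns a three-channel confocal image — nuclei (DAPI),
cytoskeleton (phalloidin, delineating the cell area) and particle signal
(e.g. AF647-labelled carriers) — into a distribution of distances from each
intracellular particle-positive pixel to the nearest nucleus, and summarizes
that distribution into three spatial classes:

* **perinuclear**: 0–5 µm from the nearest nucleus,
* **intermediate**: 5–10 µm,
* **peripheral**: more than 10 µm.

All bins are half-open on the right (`[0,5)`, `[5,10)`, `[10,∞)`), a
convention fixed once so that boundary distances are classified
deterministically; a pixel at exactly 5 µm is intermediate.

## Procedure

For one field of view the pipeline (`analyze_scene()`) runs five steps.

1. **Nuclear segmentation** (`segment_nuclei()`). Gaussian pre-smoothing
   (σ = 1 px), a global Otsu threshold, morphological opening (disc radius
   2 px), hole filling, 4-connected labelling, and removal of objects below
   50 px. Touching nuclei are *not* split: the distance to the nearest
   nuclear pixel is unchanged when two adjacent nuclei share a label, so a
   watershed step would add parameters without changing the readout.
2. **Cell-area segmentation** (`segment_cells()`). Smoothing, Otsu,
   morphological closing (disc radius 5 px, bridging gaps in cytoskeletal
   staining), hole filling. The nuclear mask is unioned in so every nucleus
   is inside the cell area. A channel with no dynamic range falls back to a
   full-frame mask with a warning — gating then removes nothing, which is
   the right degradation when the boundary stain failed.
3. **Particle detection** (`segment_particles()`). The particle channel is
   thresholded *without* smoothing, because puncta can be pixel-scale and
   smoothing dilutes them below any threshold. Otsu is the primary
   threshold; since Otsu's two-class criterion misbehaves on the
   near-unimodal histogram of a sparse-puncta image, the threshold falls
   back to the 99.5th intensity percentile whenever the Otsu foreground
   exceeds 20 % of the frame. A flat channel yields an empty mask — an
   untreated control image genuinely contains no particles, so this is a
   valid result, not an error.
4. **Artifact removal** (`clean_particle_mask()`). Particle pixels outside
   the cell mask are extracellular signal and are discarded; remaining
   4-connected components smaller than `min_component_px` (default 2 px)
   are treated as noise specks. The operation is idempotent and its output
   is always a subset of `particles ∩ cells`.
5. **Distance mapping and binning** (`compute_distance_map()`,
   `to_microns()`, `particle_distances()`, `bin_summary()`). The exact
   Euclidean distance transform of the nuclear mask assigns every pixel its
   straight-line distance (pixel units) to the nearest nuclear *pixel* —
   distance to the nuclear region, not its centroid, so pixels inside a
   nucleus have distance 0 and are perinuclear by definition. Distances are
   scaled by the pixel size (default calibration 0.15537 µm/px, always
   overridable per image) and every particle-positive pixel contributes one
   count — binary weighting, not intensity weighting.

Per-image percentages are computed first and then averaged (mean ± sample
SD) across the images of a condition, grouped by dosage label and
timepoint (`aggregate_conditions()`). Images are the biological replicates;
normalizing per image before averaging prevents fields with more particle
signal from dominating a condition. Images with no nuclei or no
intracellular particle pixels have undefined percentages and are excluded
from aggregation with a warning.

```{r example}
spec <- scene_spec(seed = 42, n_particle_pixels = 2000,
                   radial_weights = c(0.5, 0.3, 0.2),
                   dilate_particles = TRUE,  # 2x2 puncta, see below
                   meta = list(image_id = "demo", dosage_label = "high",
                               timepoint_h = 6))
gen <- generate_scene(spec)
res <- analyze_scene(gen$scene)
res$summary
round(gen$truth$true_bin_pct, 2)  # generating truth for comparison
```

## Why the distance transform is trusted

The Euclidean distance map is delegated to `EBImage::distmap()`. Its
exactness is not assumed: the test suite compares it against an exhaustive
*O(pixels × nuclear pixels)* nearest-nuclear-pixel search on hundreds of
random grids up to 32×32 and requires equality with zero tolerance. The
brute-force oracle is implemented independently in the tests, so the two
routes cannot share a defect.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `smoothing_sigma` | 1 | px | suppresses shot noise without moving edges |
| `opening_radius_px` | 2 | px | removes sub-nuclear debris from the DAPI mask |
| `min_nucleus_area_px` | 50 | px | rejects stain specks; ~1.2 µm² at the default scale |
| `closing_radius_px` | 5 | px | bridges gaps in the phalloidin boundary |
| `min_component_px` | 2 | px | single-pixel components are indistinguishable from noise in real images |
| `fallback_quantile` | 0.995 | — | sparse puncta occupy well under 0.5 % of a frame |
| `max_otsu_foreground` | 0.20 | — | an Otsu foreground above 20 % on a puncta channel signals bimodality failure |
| `bin_edges_um` | 5, 10 | µm | the perinuclear/intermediate/peripheral convention |
| `bin_width_um` | 0.5 | µm | resolves the 0–10 µm region at the default pixel scale |
| `max_edge_um` | 30 | µm | last finite histogram edge; beyond it one open-ended bin |
| `pixel_size_um` | 0.15537 | µm/px | default confocal calibration, overridable per image |

The segmentation thresholds are decisions, not reconstructions: published
workflows of this kind rarely state their Fiji threshold settings, and the
scientific content lies downstream in the distance analysis. Otsu was
chosen because it is parameter-free, deterministic and standard.

## The synthetic benchmark

`generate_scene()` builds scenes with known answers: non-overlapping round
cells (radius 100–120 px ≈ 15.5–18.6 µm at the default scale) placed in a
512×512 frame, one filled elliptical nucleus per cell (equivalent radius
22–30 px, axis ratio 0.75–1), and particle pixels placed cell-interior-only
by first drawing a spatial bin from the mixture weights `(p1, p2, p3)` and
then a uniform pixel, without replacement, among the cell pixels whose
*true* distance lies in that bin. This geometry leaves all three bins
non-empty (the largest within-cell distance is ≈ 13–15 µm). Channels are
rendered as background/foreground levels (nuclei 10/200, cell 10/140,
particle 5/150) with additive Gaussian noise, clipped at zero; the default
`noise_sd = 12` puts every channel at a signal-to-noise ratio of at least
about 10. The ground truth carries the exact masks and the per-pixel true
distances, which are verified against the exact distance transform at
generation time (tolerance 1e-9). Everything is a pure function of the spec
including its seed, and the caller's RNG stream is left untouched.

Two points about what passing the benchmark does and does not show:

* Synthetic puncta are single pixels by default. The default artifact
  filter (`min_component_px = 2`) would remove them as noise — correctly,
  by its own definition. End-to-end recovery tests therefore either
  generate puncta dilated to 2×2 blocks (`dilate_particles = TRUE`) or
  disable the component filter (`min_component_px = 1`) on noise-free
  scenes, where there are no specks to remove. On real images, whose puncta
  are spread by the point-spread function over several pixels, the default
  filter is the right one. Note that 2×2 dilation slightly distorts the
  realized mixture relative to the nominal weights (companion pixels can
  fall in the neighbouring bin), which is why recovery against *nominal*
  weights uses the undilated configuration.
* The generator does not model the optical point-spread function,
  photobleaching, uneven illumination, out-of-focus light or 3D structure.
  Passing it validates the measurement chain — segmentation, exact distance
  mapping, scaling, binning, aggregation — not the biology of any real
  image set.

`generate_micrograph()` plays the same role for morphometry: bright,
non-overlapping, mildly elliptical particles (eccentricity 0–0.4) on a dark
background, with equivalent diameters drawn from a truncated normal
(default mean 99 nm, SD 5 nm) at 5 nm/px. The per-particle truth table
carries the continuous-geometry diameter and circularity (Ramanujan's
ellipse perimeter). The default 100 particles per field pooled over five
fields reproduce the typical population size of a dry-state micrograph
analysis (~500 particles).

## Morphometry conventions

`detect_particles()` mirrors the ImageJ-style analysis convention:
threshold, label, exclude border-touching objects (partial particles bias
the size distribution low or high depending on where they are clipped),
drop objects under 10 px, then per object report area, perimeter,
equivalent diameter `2·√(A/π)·pixel_size` and circularity `4πA/P²`. The
perimeter uses the Crofton 4-direction estimator computed from the 2×2
pixel-configuration histogram; a naive boundary-pixel count systematically
overestimates the perimeter of digitized smooth shapes and would bias
circularity low. Digitization can still push circularity slightly above 1
for small disks, so it is capped at 1, again following the ImageJ
convention. Tests require the circularity of generated digital disks to
approach 1 (within 0.1 by radius 64 px).

## Payload and dose arithmetic

`plasmids_per_particle()` computes the average number of plasmids in one
particle from its dry geometry and composition:

N = [ρ · (π/6) d³ · w/(1+w)] / (L·m_bp / N_A)

where *d* is the dry-state diameter, ρ the dry particle density, *w* the
pDNA:albumin mass loading, *L* the plasmid length in bp, m_bp the average
molar mass per base pair and N_A Avogadro's number. The pDNA fraction of
total dry mass is taken as `w/(1+w)` — mass conservation for a particle
made of albumin plus pDNA. Defaults (d = 99 nm, ρ = 1.35 g/cm³,
m_bp = 650 g/mol, L = 3487 bp for an eGFP plasmid; ~6800 bp selectable for
luciferase) are typical physical values; none is a fitted quantity.
Published plasmid-count figures for comparable formulations (28 per
particle at 10 % w/w, 99 at 40 % w/w) rest on compositional assumptions
that were not published with them; under the defaults here the calculator
gives ≈ 17 at 10 % w/w and d = 100 nm, and no single parameter set we
examined reproduces both published values, so they are documented for
context rather than asserted as reference outputs.

`dose_design()` and `pdna_mass_per_well()` encode the matched-mass design:
mass per well is exactly bilinear, `M = M_base · (w/w_base) · k`, with the
baseline 10 % w/w loading at 1× dosage (70 000 particles per cell)
delivering 250 ng/well. The two orthogonal paths to any target mass —
raising loading at fixed dosage, or dosage at fixed loading — agree to
machine precision, which is what makes "same pDNA mass, different particle
number" comparisons well defined. `matched_mass_grid()` emits the paired
conditions and flags masses whose loading path would exceed the 40 % w/w
stability bound as loading-path-infeasible.

## Numerical and degenerate-input choices

* **No-contrast channels.** Nuclei: hard error (an image without nuclear
  signal cannot be analyzed). Cell: full-frame fallback with a warning.
  Particle: empty mask (valid control).
* **Empty inputs.** Empty particle masks give empty distance vectors;
  empty distance vectors give flagged empty summaries that aggregation
  skips with a warning; an empty nuclei mask raises a "no-nuclei" error.
* **Determinism.** No step uses randomness; re-running any stage on
  identical input produces bit-identical masks and byte-identical CSVs
  (fixed number formatting, fixed line endings, rows sorted by pixel
  coordinates).
* **Coordinates.** Row-major pixel indices; a mask pixel covers its unit
  square; 2D single-plane analysis with square pixels.
* **Test problem sizes.** The suites run scenes of 512×512 px with
  500–5000 particle pixels, 200 random distance-map grids up to 32×32, and
  micrograph populations of 500 particles over five fields — sizes at which
  every stochastic tolerance (binomial sampling error at n ≥ 5000, ±1 nm
  on a 99 ± 5 nm population) is comfortably resolved.

## Known limitations

* Particles are assigned to the nearest nucleus in the field, not to the
  nucleus of their own cell; with touching or adjacent cells a particle can
  be claimed by a neighbour's nucleus. Per-cell assignment would require
  instance segmentation of cells, which is out of scope.
* The analysis is 2D; distances in a single confocal plane underestimate
  true 3D distances for out-of-plane particles.
* Binary per-pixel counting ignores intensity saturation and PSF blooming;
  a large bright aggregate contributes by its area, not its brightness.
* The segmentation defaults assume dark-background fluorescence with
  bright objects; transmitted-light or inverted-contrast images need
  channel-specific preprocessing before entering the pipeline.
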