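#' @title Payload arithmetic and matched-mass dose design
#' @description Plasmids-per-particle estimation from particle geometry,
#'   density and nucleic-acid loading, and the matched-pDNA-mass
#'   loading-by-dosage experimental design grid.
#' @name payload_dose
NULL

.AVOGADRO <- 6.02214076e23

#' Describe a nucleic-acid-loaded protein nanoparticle formulation
#'
#' Loading is expressed on the albumin basis (`w` = pDNA mass per unit
#' albumin mass, e.g. 0.10 for a "10% w/w" formulation); the pDNA fraction
#' of total dry particle mass is then `w / (1 + w)` by mass conservation
#' (particle = albumin + pDNA).
#'
#' @param diameter_nm dry-state particle diameter in nm (default 99, the
#'   as-jetted population mean).
#' @param density_g_cm3 dry particle density in g/cm^3 (default 1.35,
#'   typical for dry protein).
#' @param loading_w_per_w pDNA mass per albumin mass (>= 0, <= 1; loadings
#'   above 0.40 destabilize jetting and are outside the validated range but
#'   are not rejected here).
#' @param plasmid_length_bp plasmid length in base pairs (default 3487,
#'   an eGFP plasmid; ~6800 for a luciferase plasmid).
#' @param mass_per_bp_g_mol average molar mass per base pair (default
#'   650 g/mol).
#' @return an object of class `ParticleComposition`.
#' @export
particle_composition <- function(diameter_nm = 99, density_g_cm3 = 1.35,
                                 loading_w_per_w = 0.10,
                                 plasmid_length_bp = 3487,
                                 mass_per_bp_g_mol = 650) {
  num1 <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop("'", nm, "' must be a single positive number")
    x
  }
  num1(diameter_nm, "diameter_nm")
  num1(density_g_cm3, "density_g_cm3")
  num1(plasmid_length_bp, "plasmid_length_bp")
  num1(mass_per_bp_g_mol, "mass_per_bp_g_mol")
  if (!is.numeric(loading_w_per_w) || length(loading_w_per_w) != 1L ||
      !is.finite(loading_w_per_w) || loading_w_per_w < 0 ||
      loading_w_per_w > 1)
    stop("'loading_w_per_w' must be a single value in [0, 1]")
  structure(list(diameter_nm = diameter_nm, density_g_cm3 = density_g_cm3,
                 loading_w_per_w = loading_w_per_w,
                 plasmid_length_bp = plasmid_length_bp,
                 mass_per_bp_g_mol = mass_per_bp_g_mol),
            class = "ParticleComposition")
}

#' Average number of plasmids per particle
#'
#' Computes `N = [rho * (pi/6) * d^3 * w/(1+w)] / (L * m_bp / N_A)`: the dry
#' particle mass from a spherical volume, the pDNA share of that mass on the
#' albumin-basis loading, divided by the mass of one plasmid molecule.
#'
#' Note the published plasmid-count figures for comparable formulations (28
#' per particle at 10% w/w and 99 at 40% w/w) rest on compositional
#' assumptions that were not published alongside them; under this package's
#' defaults the calculator gives about 17 at 10% w/w and d = 100 nm. The
#' published pair is therefore documented here for context, not asserted as
#' a reference output.
#'
#' @param comp a [particle_composition()].
#' @return list with `plasmids` (real-valued count) and `plasmids_rounded`
#'   (nearest integer).
#' @examples
#' comp <- particle_composition(diameter_nm = 100, loading_w_per_w = 0.10)
#' plasmids_per_particle(comp)$plasmids  # ~17.1
#' @export
plasmids_per_particle <- function(comp) {
  stopifnot(inherits(comp, "ParticleComposition"))
  d_cm <- comp$diameter_nm * 1e-7
  volume_cm3 <- (pi / 6) * d_cm^3
  particle_mass_g <- comp$density_g_cm3 * volume_cm3
  w <- comp$loading_w_per_w
  pdna_mass_g <- particle_mass_g * w / (1 + w)
  plasmid_mass_g <- comp$plasmid_length_bp * comp$mass_per_bp_g_mol / .AVOGADRO
  n <- pdna_mass_g / plasmid_mass_g
  list(plasmids = n, plasmids_rounded = round(n))
}

#' Define the baseline of the loading-by-dosage dose design
#'
#' @param baseline_loading albumin-basis pDNA loading of the baseline
#'   formulation (default 0.10, i.e. 10% w/w).
#' @param baseline_dosage_particles_per_cell particles applied per target
#'   cell at 1x dosage (default 70000).
#' @param baseline_mass_ng_per_well pDNA mass delivered per well at the
#'   baseline condition (default 250 ng, a 96-well plate).
#' @param max_loading highest loading the formulation supports (default
#'   0.40; jetting is unstable above).
#' @return an object of class `DoseDesign`.
#' @export
dose_design <- function(baseline_loading = 0.10,
                        baseline_dosage_particles_per_cell = 70000,
                        baseline_mass_ng_per_well = 250,
                        max_loading = 0.40) {
  vals <- c(baseline_loading, baseline_dosage_particles_per_cell,
            baseline_mass_ng_per_well, max_loading)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all dose-design baselines must be positive")
  if (max_loading < baseline_loading)
    stop("'max_loading' must be at least 'baseline_loading'")
  structure(list(baseline_loading = baseline_loading,
                 baseline_dosage_particles_per_cell =
                   baseline_dosage_particles_per_cell,
                 baseline_mass_ng_per_well = baseline_mass_ng_per_well,
                 max_loading = max_loading),
            class = "DoseDesign")
}

#' pDNA mass delivered per well
#'
#' The operational pairing of the dose design: mass per well scales linearly
#' in the albumin-basis loading and linearly in the particle dosage,
#' `M = M_base * (loading / loading_base) * dosage_multiple`. Either path --
#' raising the loading at fixed dosage, or the dosage at fixed loading --
#' reaches the same mass, which is what makes loading-vs-dosage comparisons
#' at matched pDNA mass possible.
#'
#' @param design a [dose_design()].
#' @param loading albumin-basis loading (> 0); vectorized.
#' @param dosage_multiple multiple of the baseline particle dosage (> 0);
#'   vectorized.
#' @return pDNA mass per well in ng.
#' @export
pdna_mass_per_well <- function(design, loading, dosage_multiple) {
  stopifnot(inherits(design, "DoseDesign"))
  if (any(!is.finite(loading)) || any(loading <= 0))
    stop("'loading' must be positive")
  if (any(!is.finite(dosage_multiple)) || any(dosage_multiple <= 0))
    stop("'dosage_multiple' must be positive")
  design$baseline_mass_ng_per_well *
    (loading / design$baseline_loading) * dosage_multiple
}

#' Matched-mass experiment grid
#'
#' For each target pDNA mass, the two orthogonal conditions that deliver it:
#' the loading path (raise loading, keep 1x dosage) and the dosage path
#' (keep the baseline loading, raise the dosage multiple). A mass whose
#' loading-path loading would exceed `design$max_loading` is reported as
#' loading-path-infeasible; the dosage path is always available.
#'
#' @param design a [dose_design()].
#' @param masses_ng numeric vector of target masses in ng/well.
#' @return a `data.frame` with columns `mass_ng`, `loading_path_loading`,
#'   `loading_path_feasible`, `dosage_path_multiple` and
#'   `dosage_path_particles_per_cell`.
#' @examples
#' d <- dose_design()
#' matched_mass_grid(d, c(250, 500, 750, 1000))
#' @export
matched_mass_grid <- function(design, masses_ng) {
  stopifnot(inherits(design, "DoseDesign"))
  if (length(masses_ng) == 0L)
    return(data.frame(mass_ng = numeric(), loading_path_loading = numeric(),
                      loading_path_feasible = logical(),
                      dosage_path_multiple = numeric(),
                      dosage_path_particles_per_cell = numeric()))
  if (any(!is.finite(masses_ng)) || any(masses_ng <= 0))
    stop("'masses_ng' must be positive")
  ratio <- masses_ng / design$baseline_mass_ng_per_well
  loading <- design$baseline_loading * ratio
  data.frame(
    mass_ng = masses_ng,
    loading_path_loading = loading,
    loading_path_feasible = loading <= design$max_loading + 1e-12,
    dosage_path_multiple = ratio,
    dosage_path_particles_per_cell =
      ratio * design$baseline_dosage_particles_per_cell)
}
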