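# Geometry, source and run configuration, single-operation sampling
# wrappers, and the simulate_run() driver around the C++ engine.

# K-shell data for the optional fluorescence-escape model:
# edge (keV), participation fraction above the edge, fluorescence yield,
# mean K-line energy (keV)
K_SHELL <- list(
  Ag = c(edge = 25.514, p = 0.846, omega = 0.830, eline = 22.6),
  I  = c(edge = 33.169, p = 0.839, omega = 0.884, eline = 28.9),
  Pt = c(edge = 78.395, p = 0.810, omega = 0.957, eline = 67.0),
  Au = c(edge = 80.725, p = 0.804, omega = 0.964, eline = 69.1)
)

#' Phantom geometry
#'
#' A homogeneous box, 10 x 10 cm^2 laterally and 12 cm deep along the
#' beam axis by default, tiled exactly by the voxel grid. Default voxels
#' are 0.5 x 0.5 x 1.0 cm (lateral x lateral x depth), giving depth bins
#' centered at 0.5, 1.5, ..., 11.5 cm.
#'
#' @param lateral_cm Lateral extents (x, y) in cm.
#' @param depth_cm Depth extent along the beam in cm.
#' @param voxel_cm Voxel edge lengths (x, y, z) in cm; must tile the box.
#' @return A `phantom_geometry`.
#' @export
phantom_geometry <- function(lateral_cm = c(10, 10), depth_cm = 12,
                             voxel_cm = c(0.5, 0.5, 1.0)) {
  stopifnot(length(lateral_cm) == 2, all(lateral_cm > 0), depth_cm > 0,
            length(voxel_cm) == 3, all(voxel_cm > 0))
  n <- c(lateral_cm, depth_cm) / voxel_cm
  if (any(abs(n - round(n)) > 1e-9))
    stop("voxel edges must exactly tile the phantom box", call. = FALSE)
  structure(list(lateral_cm = lateral_cm, depth_cm = depth_cm,
                 voxel_cm = voxel_cm, n_voxels = as.integer(round(n))),
            class = "phantom_geometry")
}

#' Source configuration
#'
#' Point source on the central axis, SSD above the entry surface,
#' illuminating a uniform disk (the circular field) on the surface.
#'
#' @param ssd_cm Source-to-surface distance in cm (> 0; default 20).
#' @param field_diameter_cm Field diameter at the surface in cm
#'   (> 0; default 5).
#' @return A `source_config`.
#' @export
source_config <- function(ssd_cm = 20, field_diameter_cm = 5) {
  stopifnot(ssd_cm > 0, field_diameter_cm > 0)
  structure(list(ssd_cm = ssd_cm, field_diameter_cm = field_diameter_cm),
            class = "source_config")
}

#' Transport run configuration
#'
#' @param n_histories Number of photon histories (divisible by
#'   `n_batches`).
#' @param n_batches Number of statistical batches (>= 2).
#' @param seed RNG seed for the run.
#' @param photon_cutoff_keV Photon transport cutoff (>= 1 keV); photons
#'   falling below it deposit their remaining energy locally.
#' @param k_fluorescence If TRUE (default), photoelectric events on
#'   Ag/I/Pt/Au above the K edge re-emit an isotropic K-fluorescence
#'   photon (tabulated participation fractions, yields and mean line
#'   energies) which is transported further, instead of depositing the
#'   full photon energy locally. Above the K edge roughly 80% of
#'   photoelectric events put most of the photon energy into a
#'   fluorescence photon with a multi-centimeter range in water, so
#'   switching this off inflates the first-bin DER well above the
#'   deterministic surface kerma-ratio bound at 220 kVp. L-fluorescence
#'   (~10 keV, sub-millimeter range) is always treated as local.
#' @return A `transport_config`.
#' @export
transport_config <- function(n_histories = 2e6, n_batches = 10, seed = 1,
                             photon_cutoff_keV = 1, k_fluorescence = TRUE) {
  stopifnot(n_histories >= n_batches, n_batches >= 2,
            photon_cutoff_keV >= 1)
  if (abs(n_histories / n_batches - round(n_histories / n_batches)) > 1e-9)
    stop("n_histories must be divisible by n_batches", call. = FALSE)
  structure(list(n_histories = n_histories, n_batches = as.integer(n_batches),
                 seed = as.integer(seed),
                 photon_cutoff_keV = photon_cutoff_keV,
                 k_fluorescence = isTRUE(k_fluorescence)),
            class = "transport_config")
}

#' Emit photons from the source toward the field disk
#'
#' Positions are the point-source location; directions point to points
#' sampled uniformly over the field disk on the entry surface (z = 0,
#' source at z = -SSD); energies are drawn from the spectrum.
#'
#' @param source A `source_config`.
#' @param spectrum A `beam_spectrum`.
#' @param n Number of photons.
#' @return Data frame with surface hit coordinates `x`, `y`, unit
#'   direction `ux`, `uy`, `uz` and `energy` (keV).
#' @export
emit_photon <- function(source, spectrum, n = 1) {
  stopifnot(inherits(source, "source_config"))
  r <- source$field_diameter_cm / 2 * sqrt(stats::runif(n))
  phi <- 2 * pi * stats::runif(n)
  x <- r * cos(phi); y <- r * sin(phi)
  nrm <- sqrt(x^2 + y^2 + source$ssd_cm^2)
  data.frame(x = x, y = y, ux = x / nrm, uy = y / nrm,
             uz = source$ssd_cm / nrm,
             energy = sample_energy(spectrum, n))
}

#' Sample free-path lengths to the next interaction
#'
#' @param mu Linear attenuation coefficient, cm^-1 (> 0).
#' @param n Number of samples.
#' @return Distances s = -ln(U)/mu in cm.
#' @export
distance_to_interaction <- function(mu, n = 1) {
  if (!is.numeric(mu) || mu <= 0)
    stop("mu must be positive", call. = FALSE)
  -log(stats::runif(n)) / mu
}

#' Sample the interaction channel
#'
#' Channel chosen with probability proportional to the partial mass
#' attenuation coefficients of the material at the photon energy.
#'
#' @param mat A `material`.
#' @param energy Photon energy (keV).
#' @param n Number of samples.
#' @return Character vector in {"photoelectric", "incoherent",
#'   "coherent"}.
#' @export
select_interaction <- function(mat, energy, n = 1) {
  p <- c(photoelectric = mass_attenuation(mat, energy, "photoelectric"),
         incoherent = mass_attenuation(mat, energy, "incoherent"),
         coherent = mass_attenuation(mat, energy, "coherent"))
  if (sum(p) <= 0) stop("all partial coefficients are zero", call. = FALSE)
  sample(names(p), n, replace = TRUE, prob = p)
}

#' Sample Compton scattering from the Klein-Nishina distribution
#'
#' Polar angle sampled by rejection from the Klein-Nishina differential
#' cross section; scattered energy follows the Compton relation
#' E' = E / (1 + (E/511)(1 - cos theta)).
#'
#' @param energy Incident photon energy (keV, > 0).
#' @param n Number of samples.
#' @return Data frame with `energy` (scattered, keV) and `angle` (polar,
#'   rad).
#' @export
klein_nishina_scatter <- function(energy, n = 1) {
  stopifnot(energy > 0)
  s <- cpp_kn_sample(energy, as.integer(n))
  data.frame(energy = s$energy, angle = acos(s$cos_theta))
}

#' Sample coherent (Rayleigh) scattering angles
#'
#' Thomson angular form, density proportional to (1 + cos^2 theta) in
#' cos theta; the photon energy is unchanged and no energy is deposited.
#'
#' @param energy Incident photon energy (keV, > 0); returned unchanged.
#' @param n Number of samples.
#' @return Data frame with `energy` and `angle` (rad).
#' @export
rayleigh_scatter <- function(energy, n = 1) {
  stopifnot(energy > 0)
  data.frame(energy = rep(energy, n),
             angle = acos(cpp_thomson_sample(as.integer(n))))
}

# Build fine energy-grid linear-attenuation tables (cm^-1) for the
# engine: 0.05 keV steps over [1, emax], edge-aware via xs_lookup.
attenuation_tables <- function(mat, emax, k_fluorescence = FALSE) {
  step <- 0.05
  egrid <- seq(1, emax + step, by = step)
  rho <- mat$density
  tabs <- list(egrid_min = egrid[1], egrid_step = step,
               mu_pe = mass_attenuation(mat, egrid, "photoelectric") * rho,
               mu_ic = mass_attenuation(mat, egrid, "incoherent") * rho,
               mu_co = mass_attenuation(mat, egrid, "coherent") * rho)
  p_fluor <- e_fluor <- numeric(length(egrid))
  if (k_fluorescence) {
    pe_mix <- tabs$mu_pe / rho
    for (s in names(mat$composition)) {
      if (is.null(K_SHELL[[s]])) next
      kd <- K_SHELL[[s]]
      above <- egrid > kd[["edge"]]
      pe_el <- mat$composition[[s]] * xs_lookup(s, egrid, "pe")
      pr <- ifelse(above & pe_mix > 0,
                   pe_el / pmax(pe_mix, 1e-300) * kd[["p"]] * kd[["omega"]],
                   0)
      p_fluor <- p_fluor + pr
      e_fluor <- ifelse(pr > 0, kd[["eline"]], e_fluor)
    }
  }
  tabs$p_fluor <- p_fluor
  tabs$e_fluor <- e_fluor
  tabs
}

#' Run a Monte Carlo depth-dose simulation
#'
#' Transports `config$n_histories` photons of the given spectrum from
#' the point source through the phantom filled with `mat`, scoring
#' deposited energy per voxel and per statistical batch under the kerma
#' approximation.
#'
#' @param spectrum A `beam_spectrum`.
#' @param mat A `material` filling the phantom.
#' @param geometry A `phantom_geometry`.
#' @param source A `source_config`.
#' @param config A `transport_config`.
#' @return A `dose_grid`: voxel edge arrays, per-voxel deposited energy
#'   (keV) per batch, energy bookkeeping per batch (emitted, deposited,
#'   escaped) and a configuration echo.
#' @export
simulate_run <- function(spectrum, mat, geometry = phantom_geometry(),
                         source = source_config(),
                         config = transport_config()) {
  stopifnot(inherits(spectrum, "beam_spectrum"), inherits(mat, "material"),
            inherits(geometry, "phantom_geometry"),
            inherits(source, "source_config"),
            inherits(config, "transport_config"))
  if (source$field_diameter_cm / 2 > min(geometry$lateral_cm) / 2)
    stop("field does not fit inside the phantom surface", call. = FALSE)
  tabs <- attenuation_tables(mat, spectrum$kvp, config$k_fluorescence)
  n <- geometry$n_voxels
  set.seed(config$seed)
  res <- cpp_transport(spectrum$energy, cumsum(spectrum$weights),
                       tabs$egrid_min, tabs$egrid_step,
                       tabs$mu_pe, tabs$mu_ic, tabs$mu_co,
                       geometry$lateral_cm[1] / 2, geometry$lateral_cm[2] / 2,
                       geometry$depth_cm, n[1], n[2], n[3],
                       source$ssd_cm, source$field_diameter_cm / 2,
                       config$n_histories, config$n_batches,
                       config$photon_cutoff_keV,
                       config$k_fluorescence, tabs$p_fluor, tabs$e_fluor)
  structure(list(
    deposit = array(res$deposit, dim = c(n, config$n_batches)),
    emitted = res$emitted, deposited = res$deposited,
    escaped = res$escaped,
    edges = list(
      x = seq(-geometry$lateral_cm[1] / 2, geometry$lateral_cm[1] / 2,
              by = geometry$voxel_cm[1]),
      y = seq(-geometry$lateral_cm[2] / 2, geometry$lateral_cm[2] / 2,
              by = geometry$voxel_cm[2]),
      z = seq(0, geometry$depth_cm, by = geometry$voxel_cm[3])),
    material = mat, geometry = geometry, source = source, config = config,
    kvp = spectrum$kvp
  ), class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %s, %g kVp, %g histories in %d batches\n",
              x$material$name, x$kvp, x$config$n_histories,
              x$config$n_batches))
  cat(sprintf("  voxels %d x %d x %d; deposited %.4g keV (%.1f%% of emitted)\n",
              dim(x$deposit)[1], dim(x$deposit)[2], dim(x$deposit)[3],
              sum(x$deposited), 100 * sum(x$deposited) / sum(x$emitted)))
  invisible(x)
}
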