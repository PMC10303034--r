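# Filtered kilovoltage x-ray tube spectra.
#
# The source term of the whole study: a Kramers-law bremsstrahlung
# continuum at the tube potential, hardened by the stated added
# filtration (2.4 mm Al at 105 kVp; 1 mm Al + 1.2 mm Cu at 220 kVp).
# Characteristic anode lines are not modelled: the treatment-head
# geometry and inherent filtration that set their intensity are not
# published, and the continuum-only model is the main documented source
# of model dependence in reproduced DER values.

FILTER_DENSITY <- c(Al = 2.70, Cu = 8.96)  # g/cm^3, fixed

#' A filter layer
#'
#' @param material Element symbol of the attenuator ("Al" or "Cu", or any
#'   element with table coverage if `density` is given).
#' @param thickness_mm Thickness in mm (> 0).
#' @param density Attenuator density in g/cm^3; defaults to Al 2.70 or
#'   Cu 8.96.
#' @return A `filter_layer`.
#' @export
filter_layer <- function(material, thickness_mm, density = NULL) {
  if (!is.numeric(thickness_mm) || length(thickness_mm) != 1 ||
      thickness_mm <= 0)
    stop("filter thickness must be a single positive number (mm)",
         call. = FALSE)
  xs_table(material)
  if (is.null(density)) {
    if (!material %in% names(FILTER_DENSITY))
      stop("no default density for filter material '", material,
           "'; supply `density`", call. = FALSE)
    density <- FILTER_DENSITY[[material]]
  }
  structure(list(material = material, thickness_mm = thickness_mm,
                 density = density), class = "filter_layer")
}

#' Construct a beam spectrum
#'
#' @param kvp Tube potential in kV.
#' @param energy Strictly increasing photon-energy bin centers in keV,
#'   all within [1, kvp] (1 keV is the photon transport cutoff).
#' @param weights Non-negative relative photon numbers per bin; stored
#'   normalized to sum 1.
#' @param filtration List of [filter_layer()]s already applied (metadata).
#' @return A `beam_spectrum`.
#' @export
beam_spectrum <- function(kvp, energy, weights, filtration = list()) {
  if (length(energy) != length(weights))
    stop("energy and weights must have equal length", call. = FALSE)
  if (is.unsorted(energy, strictly = TRUE))
    stop("energy bin centers must be strictly increasing", call. = FALSE)
  if (min(energy) < 1)
    stop("bin centers below the 1 keV photon cutoff", call. = FALSE)
  if (max(energy) > kvp)
    stop("bin centers above the tube potential", call. = FALSE)
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative with positive sum", call. = FALSE)
  structure(list(kvp = kvp, energy = energy,
                 weights = weights / sum(weights), filtration = filtration),
            class = "beam_spectrum")
}

#' @export
print.beam_spectrum <- function(x, ...) {
  filt <- if (length(x$filtration) == 0) "none" else
    paste(vapply(x$filtration, function(f)
      sprintf("%g mm %s", f$thickness_mm, f$material), ""), collapse = " + ")
  cat(sprintf("<beam_spectrum> %g kVp, %d bins [%g, %g] keV\n",
              x$kvp, length(x$energy), min(x$energy), max(x$energy)))
  cat(sprintf("  mean energy %.2f keV, filtration: %s\n",
              mean_energy(x), filt))
  invisible(x)
}

#' Kramers-law photon-number density
#'
#' Unnormalized thick-target bremsstrahlung photon-number spectrum
#' N(E) proportional to Z (E_max - E) / E.
#'
#' @param energy Photon energy (keV), vectorized.
#' @param kvp Tube potential (kV); E_max = kvp.
#' @param anode_z Anode atomic number (default tungsten, 74).
#' @return Relative photon number per unit energy (zero above kvp).
#' @export
kramers_law <- function(energy, kvp, anode_z = 74) {
  stopifnot(all(energy > 0))
  pmax(anode_z * (kvp - energy) / energy, 0)
}

#' Unfiltered Kramers tube spectrum
#'
#' @param kvp Tube potential in kV, in [40, 300].
#' @param anode_z Anode atomic number (default tungsten, 74).
#' @param n_bins Number of energy bins (>= 10). Defaults to 1 keV-wide
#'   bins from the 1 keV cutoff up to kvp.
#' @return A `beam_spectrum` with weights following the Kramers law at
#'   the bin centers.
#' @export
kramers_spectrum <- function(kvp, anode_z = 74, n_bins = NULL) {
  if (!is.numeric(kvp) || length(kvp) != 1 || kvp < 40 || kvp > 300)
    stop("kvp must lie in [40, 300] kV", call. = FALSE)
  if (is.null(n_bins)) n_bins <- round(kvp - 1)
  if (n_bins < 10) stop("n_bins must be at least 10", call. = FALSE)
  edges <- seq(1, kvp, length.out = n_bins + 1)
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  beam_spectrum(kvp, centers, kramers_law(centers, kvp, anode_z))
}

#' Harden a spectrum through filter layers
#'
#' Each weight is multiplied by exp(-sum_i (mu/rho)_i(E) rho_i t_i) and
#' the spectrum is renormalized; the mean energy strictly increases for
#' any filter of positive thickness (beam hardening).
#'
#' @param spectrum A `beam_spectrum`.
#' @param filters List of [filter_layer()]s (an empty list returns the
#'   spectrum unchanged).
#' @return The filtered `beam_spectrum`.
#' @export
apply_filtration <- function(spectrum, filters) {
  stopifnot(inherits(spectrum, "beam_spectrum"))
  if (inherits(filters, "filter_layer")) filters <- list(filters)
  w <- spectrum$weights
  for (f in filters) {
    if (!inherits(f, "filter_layer")) stop("filters must be filter_layer objects",
                                           call. = FALSE)
    mu_rho <- xs_lookup(f$material, spectrum$energy, "pe") +
      xs_lookup(f$material, spectrum$energy, "incoh") +
      xs_lookup(f$material, spectrum$energy, "coh")
    w <- w * exp(-mu_rho * f$density * f$thickness_mm / 10)
  }
  beam_spectrum(spectrum$kvp, spectrum$energy, w,
                c(spectrum$filtration, filters))
}

#' Mean energy of a spectrum
#'
#' @param spectrum A `beam_spectrum`.
#' @return Photon-number-weighted mean energy in keV.
#' @export
mean_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "beam_spectrum"))
  sum(spectrum$energy * spectrum$weights)
}

#' Sample photon energies from a spectrum
#'
#' Inverse-CDF sampling over the spectrum bins using R's random number
#' stream (seedable via [set.seed()]); returns bin-center energies.
#'
#' @param spectrum A `beam_spectrum`.
#' @param n Number of samples (>= 1).
#' @return Numeric vector of energies in keV.
#' @export
sample_energy <- function(spectrum, n) {
  stopifnot(inherits(spectrum, "beam_spectrum"), n >= 1)
  if (abs(sum(spectrum$weights) - 1) > 1e-12)
    stop("spectrum weights are not normalized", call. = FALSE)
  cdf <- cumsum(spectrum$weights)
  idx <- findInterval(stats::runif(n), cdf, left.open = TRUE) + 1L
  spectrum$energy[idx]
}

#' Half-value layer of a spectrum
#'
#' Smallest attenuator thickness t with
#' sum w(E) E exp(-mu(E) t) = 0.5 sum w(E) E (energy-fluence-weighted
#' narrow-beam transmission), solved by bracketing and bisection to
#' 1e-4 mm.
#'
#' @param spectrum A `beam_spectrum`.
#' @param attenuator Element symbol with table coverage ("Al" or "Cu"
#'   have default densities).
#' @param density Attenuator density (g/cm^3); defaults as in
#'   [filter_layer()].
#' @return Thickness in mm.
#' @export
half_value_layer <- function(spectrum, attenuator, density = NULL) {
  stopifnot(inherits(spectrum, "beam_spectrum"))
  if (sum(spectrum$weights) <= 0) stop("non-positive spectrum", call. = FALSE)
  if (is.null(density)) {
    if (!attenuator %in% names(FILTER_DENSITY))
      stop("no default density for '", attenuator, "'; supply `density`",
           call. = FALSE)
    density <- FILTER_DENSITY[[attenuator]]
  }
  mu_rho <- xs_lookup(attenuator, spectrum$energy, "pe") +
    xs_lookup(attenuator, spectrum$energy, "incoh") +
    xs_lookup(attenuator, spectrum$energy, "coh")
  mu_mm <- mu_rho * density / 10  # per mm
  we <- spectrum$weights * spectrum$energy
  trans <- function(t) sum(we * exp(-mu_mm * t)) / sum(we)
  hi <- 1
  while (trans(hi) > 0.5) hi <- hi * 2
  lo <- 0
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (trans(mid) > 0.5) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Write a spectrum as two-column text
#'
#' @param spectrum A `beam_spectrum`.
#' @param path Output file.
#' @export
write_spectrum <- function(spectrum, path) {
  filt <- if (length(spectrum$filtration) == 0) "none" else
    paste(vapply(spectrum$filtration, function(f)
      sprintf("%gmm%s", f$thickness_mm, f$material), ""), collapse = "+")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("# kvp %g", spectrum$kvp),
               sprintf("# filtration %s", filt),
               "# columns: energy_keV weight"), con)
  utils::write.table(data.frame(spectrum$energy, spectrum$weights), con,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a spectrum written by [write_spectrum()]
#'
#' @param path Input file.
#' @return A `beam_spectrum` (filtration metadata is not reconstructed).
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  kvp <- as.numeric(sub("# kvp ", "", lines[startsWith(lines, "# kvp")]))
  dat <- utils::read.table(text = lines[!startsWith(lines, "#")],
                           col.names = c("energy", "weight"))
  beam_spectrum(kvp, dat$energy, dat$weight)
}

#' The two filtered study beams
#'
#' The 105 kVp beam hardened by 2.4 mm Al, and the 220 kVp beam by
#' 1 mm Al + 1.2 mm Cu, both as Kramers continua from a tungsten anode.
#'
#' @param kvp 105 or 220.
#' @param n_bins Optional bin count passed to [kramers_spectrum()].
#' @return A filtered `beam_spectrum`.
#' @export
study_beam <- function(kvp = c(105, 220), n_bins = NULL) {
  kvp <- match.arg(as.character(kvp[1]), c("105", "220"))
  if (kvp == "105") {
    apply_filtration(kramers_spectrum(105, n_bins = n_bins),
                     list(filter_layer("Al", 2.4)))
  } else {
    apply_filtration(kramers_spectrum(220, n_bins = n_bins),
                     list(filter_layer("Al", 1.0), filter_layer("Cu", 1.2)))
  }
}
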