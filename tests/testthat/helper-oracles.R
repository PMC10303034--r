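# Independent oracles used across the suite.

# Raw elemental table access: reads the shipped text tables directly and
# interpolates log-log on the full grid, bypassing the package's
# edge-aware lookup machinery.
raw_xs <- function(symbol, energy,
                   column = c("tot", "pe", "incoh", "coh", "mu_en")) {
  column <- match.arg(column)
  path <- system.file("extdata", "xs", paste0(symbol, ".txt"),
                      package = "npder")
  tab <- read.table(path, comment.char = "#",
                    col.names = c("energy", "pe", "incoh", "coh", "mu_en"))
  y <- if (column == "tot") tab$pe + tab$incoh + tab$coh else tab[[column]]
  exp(approx(log(tab$energy), log(y), xout = log(energy))$y)
}

# Published NIST (Hubbell-Seltzer) reference values for liquid water,
# cm^2/g, at the seven reference energies.
NIST_WATER <- data.frame(
  energy = c(10, 30, 50, 80, 100, 150, 200),
  mu_rho = c(5.329, 0.3756, 0.2269, 0.1837, 0.1707, 0.1505, 0.1370),
  mu_en_rho = c(4.944, 0.1557, 0.04223, 0.02597, 0.02546, 0.02764, 0.02967))

# Normalized Klein-Nishina probability of cos(theta) falling in
# [lo, hi] at energy E (keV), by numerical integration.
kn_bin_prob <- function(E, lo, hi) {
  dens <- function(c) {
    eps <- 1 / (1 + (E / 510.99895) * (1 - c))
    eps^2 * (eps + 1 / eps - (1 - c^2))
  }
  total <- integrate(dens, -1, 1, rel.tol = 1e-10)$value
  integrate(dens, lo, hi, rel.tol = 1e-10)$value / total
}

# Compton kinematic bounds on the scattered photon energy.
compton_min_energy <- function(E) E / (1 + 2 * E / 510.99895)
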