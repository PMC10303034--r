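# Source geometry, samplers and the transport engine physics oracles.

test_that("emitted photons populate the field disk uniformly", {
  src <- source_config(ssd_cm = 20, field_diameter_cm = 5)
  set.seed(11)
  ph <- emit_photon(src, study_beam(105), 1e5)
  r2 <- ph$x^2 + ph$y^2
  expect_true(all(r2 <= 2.5^2))
  expect_true(all(abs(ph$ux^2 + ph$uy^2 + ph$uz^2 - 1) < 1e-9))
  # uniform-disk moments: E[x] = 0, E[r^2] = R^2/2 (RMS radius R/sqrt(2))
  expect_lt(abs(mean(ph$x)), 4 * 1.25 / sqrt(1e5))
  expect_lt(abs(mean(r2) - 2.5^2 / 2), 4 * (2.5^2 / sqrt(12)) / sqrt(1e5))
  # a vanishing field collapses onto the beam axis
  set.seed(12)
  axis <- emit_photon(source_config(20, 1e-9), study_beam(105), 10)
  expect_true(all(abs(axis$uz - 1) < 1e-12))
})

test_that("point-source fluence falls off as inverse square", {
  # uniform disk at the surface (20 cm): doubling the distance scales
  # the lateral hit pattern by 2, so the photon density through a fixed
  # small central area drops fourfold
  set.seed(13)
  ph <- emit_photon(source_config(20, 5), study_beam(105), 4e5)
  r_surface <- sqrt(ph$x^2 + ph$y^2)
  t40 <- 40 / 20  # path scaling from z = 0 to the plane 40 cm out
  n20 <- sum(r_surface <= 0.5)
  n40 <- sum(r_surface * t40 <= 0.5)
  ratio <- n20 / n40
  se <- ratio * sqrt(1 / n20 + 1 / n40)
  expect_lt(abs(ratio - 4), 4 * se)
})

test_that("free paths are exponential with mean 1/mu", {
  set.seed(14)
  s <- distance_to_interaction(0.2, 1e6)
  expect_lt(abs(mean(s) - 5), 4 * 5 / sqrt(1e6))
  p_tail <- mean(s > 5)
  expect_lt(abs(p_tail - exp(-1)),
            4 * sqrt(exp(-1) * (1 - exp(-1)) / 1e6))
  expect_error(distance_to_interaction(0), "positive")
})

test_that("interaction channels follow the partial coefficients", {
  au40 <- nanoparticle_mixture("gold", 40)
  set.seed(15)
  ch <- select_interaction(au40, 30, 1e4)
  expect_equal(names(which.max(table(ch))), "photoelectric")
  set.seed(16)
  ch_w <- select_interaction(water(), 200, 1e4)
  expect_equal(names(which.max(table(ch_w))), "incoherent")
  # multinomial frequencies vs the partial-coefficient ratios
  p <- vapply(c("photoelectric", "incoherent", "coherent"), function(pr)
    mass_attenuation(water(), 60, pr), numeric(1))
  p <- p / sum(p)
  set.seed(17)
  ch60 <- select_interaction(water(), 60, 1e5)
  for (nm in names(p)) {
    f <- mean(ch60 == nm)
    expect_lt(abs(f - p[[nm]]), 4 * sqrt(p[[nm]] * (1 - p[[nm]]) / 1e5))
  }
})

test_that("Compton kinematics and the Klein-Nishina sampler are correct", {
  # scattered energy is the Compton formula of the sampled angle and
  # lies in the kinematically allowed band
  for (E in c(30, 100, 220, 511)) {
    set.seed(18)
    s <- klein_nishina_scatter(E, 2e4)
    back <- E / (1 + (E / 510.99895) * (1 - cos(s$angle)))
    expect_equal(s$energy, back, tolerance = 1e-12)
    expect_true(all(s$energy <= E + 1e-12))
    expect_true(all(s$energy >= compton_min_energy(E) - 1e-12))
  }
  # 180-degree backscatter of a 511 keV photon keeps one third of it
  expect_equal(511 / (1 + (511 / 510.99895) * 2), 511 / 3, tolerance = 1e-4)

  # chi-square of sampled angles against the integrated KN density at
  # 100 keV, alpha = 0.001
  set.seed(19)
  cth <- klein_nishina_scatter(100, 1e6)
  edges <- seq(-1, 1, length.out = 21)
  counts <- hist(cos(cth$angle), breaks = edges, plot = FALSE)$counts
  probs <- vapply(seq_len(20), function(i)
    kn_bin_prob(100, edges[i], edges[i + 1]), numeric(1))
  chi <- sum((counts - 1e6 * probs)^2 / (1e6 * probs))
  expect_gt(pchisq(chi, df = 19, lower.tail = FALSE), 0.001)
})

test_that("Rayleigh scattering is elastic with the Thomson angular form", {
  set.seed(20)
  s <- rayleigh_scatter(75, 1e6)
  expect_true(all(s$energy == 75))
  c <- cos(s$angle)
  # (1 + cos^2) is symmetric: mean cos = 0, P(theta < pi/2) = 1/2;
  # var(cos) = 2/5 under the Thomson form
  expect_lt(abs(mean(c)), 4 * sqrt(0.4 / 1e6))
  expect_lt(abs(mean(c > 0) - 0.5), 4 * sqrt(0.25 / 1e6))
  expect_equal(var(c), 0.4, tolerance = 0.01)
})

test_that("energy is conserved exactly in every batch", {
  cfg <- transport_config(n_histories = 1e5, n_batches = 5, seed = 21)
  g <- simulate_run(study_beam(105), water(), config = cfg)
  expect_true(all(abs(g$deposited + g$escaped - g$emitted) /
                    g$emitted < 1e-6))
  # voxel deposits add up to the per-batch deposited energy
  for (b in seq_len(5))
    expect_equal(sum(g$deposit[, , , b]), g$deposited[b],
                 tolerance = 1e-9)
})

test_that("a pure photoelectric medium reproduces Beer-Lambert", {
  # custom engine tables: constant mu = 0.2/cm, photoelectric only;
  # quasi-parallel beam (huge SSD) so divergence does not bend the fit
  mu <- 0.2
  ngrid <- 1500
  set.seed(22)
  res <- npder:::cpp_transport(
    spec_energy = 60, spec_cdf = 1,
    egrid_min = 1, egrid_step = 0.05,
    mu_pe = rep(mu, ngrid), mu_ic = rep(0, ngrid), mu_co = rep(0, ngrid),
    half_x = 5, half_y = 5, depth = 12, nx = 1, ny = 1, nz = 24,
    ssd = 1e5, field_radius = 0.5,
    n_histories = 2e5, n_batches = 2, cutoff = 1,
    k_fluor = FALSE, p_fluor = rep(0, ngrid), e_fluor = rep(0, ngrid))
  dep <- array(res$deposit, dim = c(1, 1, 24, 2))
  counts <- apply(dep, 3, sum)
  z <- seq(0.25, 11.75, by = 0.5)
  keep <- 1:16
  fit <- lm(log(counts[keep]) ~ z[keep])
  expect_equal(unname(-coef(fit)[2]), mu, tolerance = 0.02)
})

test_that("identical seed and config give bit-identical dose grids", {
  cfg <- transport_config(n_histories = 5e4, n_batches = 2, seed = 23)
  g1 <- simulate_run(study_beam(220), nanoparticle_mixture("gold", 18),
                     config = cfg)
  g2 <- simulate_run(study_beam(220), nanoparticle_mixture("gold", 18),
                     config = cfg)
  expect_identical(g1$deposit, g2$deposit)
  expect_identical(g1$escaped, g2$escaped)
})
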