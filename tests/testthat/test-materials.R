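# Material composition, mixture rule and interaction coefficients.

test_that("water has the textbook composition", {
  w <- water()
  expect_equal(w$density, 1.000)
  expect_equal(w$composition[["H"]], 0.1119, tolerance = 1e-3)
  expect_equal(w$composition[["O"]], 0.8881, tolerance = 1e-3)
  expect_lt(abs(sum(w$composition) - 1), 1e-12)
})

test_that("nanoparticle mixtures follow the added-mass model", {
  expect_equal(nanoparticle_mixture("gold", 0)$composition,
               water()$composition)
  au40 <- nanoparticle_mixture("gold", 40)
  expect_equal(au40$composition[["Au"]], 40 / 1040, tolerance = 1e-9)
  expect_equal(au40$density, 1.040)
  # iron oxide resolves to Fe3O4 stoichiometric mass split
  fe <- nanoparticle_mixture("iron_oxide", 40)
  f_np <- 40 / 1040
  expect_equal(fe$composition[["Fe"]] / f_np, 3 * 55.845 / 231.53,
               tolerance = 1e-4)
  fe2 <- nanoparticle_mixture("iron_oxide", 40, iron_oxide_form = "Fe2O3")
  expect_equal(fe2$composition[["Fe"]] / f_np, 2 * 55.845 / 159.69,
               tolerance = 1e-4)
  expect_error(nanoparticle_mixture("lead", 10), "unknown")
  expect_error(nanoparticle_mixture("gold", -1), "non-negative")
  # composition closure for all study materials and concentrations
  for (m in c("gold", "platinum", "iodine", "silver", "iron_oxide"))
    for (C in c(3, 7, 18, 30, 40))
      expect_lt(abs(sum(nanoparticle_mixture(m, C)$composition) - 1), 1e-9)
})

test_that("Bragg additivity holds exactly for a 50/50 mixture", {
  mix <- material("AlCu", 4.0, c(Al = 0.5, Cu = 0.5))
  for (E in c(15, 50, 120, 250)) {
    expect_equal(mass_attenuation(mix, E),
                 0.5 * (raw_xs("Al", E) + raw_xs("Cu", E)),
                 tolerance = 1e-3)
  }
})

test_that("water coefficients agree with NIST within 2%", {
  w <- water()
  for (i in seq_len(nrow(NIST_WATER))) {
    E <- NIST_WATER$energy[i]
    expect_equal(mass_attenuation(w, E), NIST_WATER$mu_rho[i],
                 tolerance = 0.02)
    expect_equal(mass_energy_absorption(w, E), NIST_WATER$mu_en_rho[i],
                 tolerance = 0.02)
  }
})

test_that("absorption edges are respected by the interpolation", {
  au <- material("gold", 19.3, c(Au = 1))
  pe_below <- mass_attenuation(au, 80, "photoelectric")
  pe_above <- mass_attenuation(au, 81, "photoelectric")
  expect_gt(pe_above / pe_below, 3)  # K-edge jump at 80.7 keV
  # left/right limits: values just either side of the edge stay on
  # their own branch instead of being smeared across it
  edge <- element_info("Au")$edges
  k <- edge[length(edge)]
  left <- mass_attenuation(au, k * (1 - 5e-5), "photoelectric")
  right <- mass_attenuation(au, k * (1 + 5e-5), "photoelectric")
  # left limit continues the sub-edge E^-3 trend, right limit jumps
  expect_equal(left / pe_below, (80 / k)^3, tolerance = 0.05)
  expect_gt(right / left, 3)
})

test_that("energy absorption is bounded by attenuation and enhanced by gold", {
  for (m in list(water(), nanoparticle_mixture("gold", 40),
                 nanoparticle_mixture("iodine", 18))) {
    E <- c(2, 5, 10, 20, 50, 81, 100, 200, 299)
    expect_true(all(mass_energy_absorption(m, E) <=
                      mass_attenuation(m, E) * (1 + 1e-9)))
  }
  # 40 mg/mL gold multiplies water's mu_en at 60 keV more than fourfold
  au40 <- nanoparticle_mixture("gold", 40)
  expect_gt(mass_energy_absorption(au40, 60) /
              mass_energy_absorption(water(), 60), 4)
})

test_that("attenuation grows with gold concentration and with density", {
  for (E in c(10, 50, 100, 140)) {
    mu <- vapply(c(0, 3, 7, 18, 30, 40), function(C)
      mass_attenuation(nanoparticle_mixture("gold", C), E), numeric(1))
    expect_true(all(diff(mu) > 0))
  }
  m1 <- material("x", 1, c(Al = 1)); m2 <- material("x", 2.7, c(Al = 1))
  expect_equal(linear_attenuation(m2, 50) / linear_attenuation(m1, 50), 2.7)
  expect_equal(linear_attenuation(water(), 50),
               mass_attenuation(water(), 50), tolerance = 1e-12)
  expect_error(mass_attenuation(water(), 500), "coverage")
  expect_error(mass_attenuation(water(), 0.5), "coverage")
})
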