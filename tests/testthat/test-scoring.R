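# Depth-dose reduction, DER computation, and summary contrasts.

# Minimal hand-built dose grid: deposits placed explicitly.
fake_grid <- function(deposit, n_histories = 100, density = 1) {
  nb <- dim(deposit)[4]
  structure(list(
    deposit = deposit,
    emitted = rep(1, nb), deposited = rep(1, nb), escaped = rep(0, nb),
    edges = list(x = seq(-5, 5, 0.5), y = seq(-5, 5, 0.5),
                 z = seq(0, 12, 1)),
    material = material("test", density, c(H = 0.1119, O = 0.8881)),
    geometry = phantom_geometry(),
    source = source_config(),
    config = transport_config(n_histories = n_histories, n_batches = nb,
                              seed = 1)),
    class = "dose_grid")
}

test_that("depth dose localizes deposits and normalizes by mass", {
  dep <- array(0, dim = c(20, 20, 12, 2))
  dep[10, 10, 3, ] <- 50  # central voxel, depth bin 2.5 cm, both batches
  cv <- depth_dose(fake_grid(dep), scoring_radius = 0.5)
  expect_equal(cv$depth_cm, seq(0.5, 11.5, 1))
  # 4 central voxels x 0.25 cm^3 x rho = 1 g scoring mass per bin,
  # 50 histories per batch
  expect_equal(cv$dose_per_history[3], 50 / 1 / 50)
  expect_true(all(cv$dose_per_history[-3] == 0))
  expect_error(depth_dose(fake_grid(dep), scoring_radius = 3), "field")
  expect_error(depth_dose(fake_grid(dep), scoring_radius = 0.1),
               "no voxel")
})

test_that("water against itself gives DER identically 1", {
  cfg <- transport_config(n_histories = 1e5, n_batches = 5, seed = 31)
  cv <- depth_dose(simulate_run(study_beam(105), water(), config = cfg))
  der <- compute_der(cv, cv)
  ok <- der$status == "ok"
  expect_true(any(ok))
  expect_true(all(der$der[ok] == 1))
  expect_equal(der$rel_unc[ok], sqrt(2) * cv$rel_se[ok])
})

test_that("batch standard errors shrink roughly as 1/sqrt(histories)", {
  mk <- function(n, seed) depth_dose(simulate_run(
    study_beam(105), water(),
    config = transport_config(n_histories = n, n_batches = 10,
                              seed = seed)))
  a <- mk(5e4, 32); b <- mk(4.5e5, 33)
  # dose per history is an invariant of n; its error scales ~ 1/sqrt(n)
  expect_equal(b$dose_per_history[1], a$dose_per_history[1],
               tolerance = 0.1)
  expect_equal(a$rel_se[1] / b$rel_se[1], 3, tolerance = 0.5)
})

test_that("kilovoltage water depth dose decays beyond the first bin", {
  cfg <- transport_config(n_histories = 4e5, n_batches = 10, seed = 34)
  cv <- depth_dose(simulate_run(study_beam(105), water(), config = cfg))
  expect_true(all(diff(cv$dose_per_history) < 0))
})

test_that("DER flags undefined bins and rejects mismatched binning", {
  dep_np <- array(0, dim = c(20, 20, 12, 2)); dep_np[10, 10, 1:2, ] <- 10
  dep_w <- array(0, dim = c(20, 20, 12, 2)); dep_w[10, 10, 1, ] <- 5
  np <- depth_dose(fake_grid(dep_np)); wa <- depth_dose(fake_grid(dep_w))
  der <- compute_der(np, wa)
  expect_equal(nrow(der), 12)  # nothing silently dropped
  expect_equal(der$der[1], 2)
  expect_true(is.na(der$der[2]))
  expect_equal(der$status[2], "zero_water_dose")
  short <- wa[1:6, ]; class(short) <- class(wa)
  expect_error(compute_der(np, short), "binning")
})

test_that("summary statistics and both contrast conventions are right", {
  flat <- data.frame(depth_cm = seq(0.5, 11.5, 1), der = 1, rel_unc = 0.01,
                     status = "ok")
  class(flat) <- c("der_curve", "data.frame")
  s <- der_summary(flat)
  expect_equal(s$max_der, 1); expect_equal(s$min_der, 1)
  expect_equal(s$der_0.5cm, 1); expect_equal(s$der_5.5cm, 1)

  # the printed-percentage convention is the plain ratio x 100: a rise
  # from 1.10 to 3.77 prints as 342.7%, from 0.64 to 0.66 as 103.1%
  ct <- der_contrast(1.10, 3.77)
  expect_equal(ct$ratio_pct, 342.7, tolerance = 1e-3)
  expect_equal(ct$increase_pct, 242.7, tolerance = 1e-3)
  ct2 <- der_contrast(0.64, 0.66)
  expect_equal(ct2$ratio_pct, 103.125, tolerance = 1e-6)
  expect_equal(ct2$increase_pct, 3.125, tolerance = 1e-6)
  expect_error(der_summary(list()), "empty")
})

test_that("summary assembles cross-concentration contrasts", {
  mk <- function(C, der1) {
    cv <- data.frame(depth_cm = seq(0.5, 11.5, 1),
                     der = c(der1, rep(1, 11)), rel_unc = 0.01,
                     status = "ok")
    class(cv) <- c("der_curve", "data.frame")
    attr(cv, "material") <- "gold"; attr(cv, "concentration") <- C
    attr(cv, "kvp") <- 105
    cv
  }
  s <- der_summary(list(mk(3, 1.10), mk(40, 3.77)))
  ct <- attr(s, "contrasts")
  expect_equal(nrow(ct), 2)
  r <- ct[ct$depth == "der_0.5cm", ]
  expect_equal(r$ratio_pct, 342.7, tolerance = 1e-3)
  expect_equal(r$c_low, 3); expect_equal(r$c_high, 40)
})
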