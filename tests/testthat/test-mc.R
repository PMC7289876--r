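test_that("a pure-air phantom absorbs nothing", {
  ph <- make_cylinder_phantom(n = 32, radius_mm = 60, hu_inside = -1000,
                              spacing_xy = 6, spacing_z = 12)
  cfg <- transport_config(n_histories = 5e3, rng_seed = 1,
                          interactions = list(compton = FALSE))
  m <- simulate_dose(ph, scan_parameters(), cfg)
  expect_true(all(m$relative_dose == 0))
  expect_equal(m$deposited_keV, 0)
  expect_gt(m$emitted_keV, 0)
})

test_that("identical seeds give bit-identical dose maps; seeds matter", {
  ph <- make_cylinder_phantom(n = 32, radius_mm = 60, spacing_xy = 6,
                              spacing_z = 12)
  cfg <- transport_config(n_histories = 2e4, rng_seed = 7)
  m1 <- simulate_dose(ph, scan_parameters(), cfg)
  m2 <- simulate_dose(ph, scan_parameters(), cfg)
  expect_identical(m1$relative_dose, m2$relative_dose)
  expect_identical(m1$deposited_keV, m2$deposited_keV)
  m3 <- simulate_dose(ph, scan_parameters(),
                      transport_config(n_histories = 2e4, rng_seed = 8))
  expect_false(identical(m1$relative_dose, m3$relative_dose))
})

test_that("energy bookkeeping: deposition never exceeds emission", {
  ph <- make_cylinder_phantom(n = 32, radius_mm = 80, spacing_xy = 6,
                              spacing_z = 12)
  for (flags in list(list(), list(follow_scatter = FALSE),
                     list(compton = FALSE))) {
    m <- simulate_dose(ph, scan_parameters(),
                       transport_config(n_histories = 2e4, rng_seed = 3,
                                        interactions = flags))
    expect_lte(m$deposited_keV, m$emitted_keV)
  }
})

test_that("following scattered photons only adds deposition", {
  ph <- make_cylinder_phantom(n = 32, radius_mm = 80, spacing_xy = 6,
                              spacing_z = 12)
  on <- simulate_dose(ph, scan_parameters(),
                      transport_config(n_histories = 2e4, rng_seed = 5))
  off <- simulate_dose(ph, scan_parameters(),
                       transport_config(n_histories = 2e4, rng_seed = 5,
                                        interactions = list(follow_scatter = FALSE)))
  expect_gte(on$deposited_keV, off$deposited_keV)
  expect_gte(sum(on$relative_dose), sum(off$relative_dose))
})

test_that("primary-only axis dose matches the analytic attenuation oracle", {
  ph <- make_cylinder_phantom(n = 64, radius_mm = 100)
  reg <- cylinder_center_region(64)
  oracle <- cylinder_axis_oracle(100)
  ests <- vapply(1:5, function(s) {
    cfg <- transport_config(n_histories = 1e5, rng_seed = s, score_boost = 4,
                            interactions = list(follow_scatter = FALSE))
    m <- simulate_dose(ph, scan_parameters(), cfg)
    mean(m$relative_dose[reg$xy, reg$xy, reg$z])
  }, numeric(1))
  se <- sd(ests) / sqrt(length(ests))
  expect_lt(abs(mean(ests) - oracle), 3 * se)
})

test_that("dose decreases with depth in an absorption-only cylinder", {
  n <- 48
  ph <- make_cylinder_phantom(n = n, radius_mm = 110, spacing_xy = 5,
                              spacing_z = 10)
  cfg <- transport_config(n_histories = 3e5, rng_seed = 11, score_boost = 4,
                          interactions = list(compton = FALSE))
  m <- simulate_dose(ph, scan_parameters(), cfg)
  cx <- (seq_len(n) - (n + 1) / 2) * 5
  R <- sqrt(outer(cx^2, cx^2, "+"))
  mid <- seq(round(0.3 * n), round(0.7 * n))
  band_mean <- function(lo, hi) {
    mask <- R >= lo & R < hi
    mean(apply(m$relative_dose[, , mid], 3, function(sl) mean(sl[mask])))
  }
  shells <- c(band_mean(90, 110), band_mean(50, 70), band_mean(0, 30))
  expect_true(all(diff(shells) < 0))
})

test_that("per-voxel uncertainty shrinks with more histories", {
  ph <- make_cylinder_phantom(n = 32, radius_mm = 80, spacing_xy = 6,
                              spacing_z = 12)
  ses <- vapply(c(1e4, 1e5), function(nh) {
    m <- simulate_dose(ph, scan_parameters(),
                       transport_config(n_histories = nh, rng_seed = 2))
    median(m$uncertainty[m$relative_dose > 0])
  }, numeric(1))
  expect_lt(ses[2], ses[1])
})

test_that("degenerate inputs are rejected", {
  ph <- make_cylinder_phantom(n = 32, radius_mm = 60, spacing_xy = 6,
                              spacing_z = 12)
  bad <- ph
  bad$spacing <- c(6, 6, 0)
  expect_error(simulate_dose(bad, scan_parameters()), "degenerate")
  expect_error(transport_config(n_histories = 0), "positive")
  expect_error(transport_config(energies_keV = 5), "10-150")
  short_helix <- transport_config(helix = list(start_z = 0, end_z = 10,
                                               pitch = 0.8, source_radius = 600))
  expect_error(simulate_dose(ph, scan_parameters(), short_helix),
               "cover the phantom")
})

test_that("air kerma scaling is linear and leaves the relative grid alone", {
  rel <- array(c(1, 0.5, 0.25, 0), dim = c(2, 2, 1))
  m <- fake_dose_map(rel)
  m$absorbed_dose <- NULL
  s <- scale_to_absorbed(m, 18.3)
  expect_equal(s$absorbed_dose[1, 1, 1], 18.3)
  expect_identical(s$relative_dose, rel)
  s2 <- scale_to_absorbed(m, 36.6)
  expect_equal(s2$absorbed_dose, 2 * s$absorbed_dose)
  expect_error(scale_to_absorbed(m, 0), "positive")
  expect_error(scale_to_absorbed(m, -3), "positive")
})
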