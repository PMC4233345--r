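test_that("Debye sum matches closed forms for one and two beads", {
  one <- bead_model(matrix(c(1, 2, 3), 1), weight = 2)
  th <- debye_intensity(one, c(0.01, 0.1, 0.3), form_factor = "point")
  expect_equal(th$I, rep(4, 3))
  two <- bead_model(rbind(c(0, 0, 0), c(10, 0, 0)), weight = 1)
  s <- c(1e-9, 0.05, 0.1, 0.3)
  th2 <- debye_intensity(two, s, form_factor = "point")
  expected <- 2 + 2 * sin(10 * s) / (10 * s)
  expected[1] <- 4
  expect_equal(th2$I, expected, tolerance = 1e-9)
})

test_that("I(0) equals the squared total weight for every form factor", {
  m <- random_bead_model(40, seed = 8, weight = 1.7)
  for (ff in c("point", "gaussian_sphere", "hard_sphere_amplitude")) {
    th <- debye_intensity(m, c(1e-9, 0.1), form_factor = ff)
    expect_equal(th$I[1], sum(m$weight)^2, tolerance = 1e-6)
    expect_true(all(th$I > 0))
  }
})

test_that("Debye intensity is invariant under rigid motions", {
  m <- random_bead_model(60, seed = 12)
  s <- seq(0.01, 0.35, length.out = 60)
  ref <- debye_intensity(m, s, form_factor = "gaussian_sphere")
  for (seed in c(1, 2)) {
    rot <- random_rotation(seed)
    moved <- bead_model(sweep(m$coords %*% t(rot), 2, c(4, -7, 2), `+`))
    th <- debye_intensity(moved, s, form_factor = "gaussian_sphere")
    expect_lt(max(abs(th$I - ref$I) / ref$I), 1e-10)
  }
})

test_that("histogram fast path agrees with the exact double sum", {
  m <- random_bead_model(500, envelope_radius = 40, seed = 7)
  s <- seq(0.005, 0.35, length.out = 100)
  exact <- debye_intensity(m, s, hist_threshold = 2000L)
  fast <- debye_intensity(m, s, hist_threshold = 100L)
  expect_lt(max(abs(fast$I - exact$I) / exact$I), 1e-3)
})

test_that("regridding reduces point count and preserves linear profiles", {
  s <- seq(0.01, 0.5, length.out = 2000)
  lin <- saxs_curve(s, 100 - 150 * s, sigma = rep(1, 2000))
  rg <- regrid_for_fit(lin, 256L)
  expect_lte(length(rg$s), 256L)
  expect_equal(rg$I, 100 - 150 * rg$s, tolerance = 1e-9)
  small <- saxs_curve(s[1:100], lin$I[1:100])
  expect_identical(regrid_for_fit(small, 256L), small)
})

test_that("fit recovers planted scale and background exactly", {
  m <- random_bead_model(100, envelope_radius = 25, seed = 3)
  s <- seq(0.005, 0.35, length.out = 500)
  th <- debye_intensity(m, s, form_factor = "gaussian_sphere")
  expd <- saxs_curve(s, 2 * th$I + 5, sigma = 0.01 * abs(2 * th$I + 5))
  f <- fit_to_data(th, expd, background_bounds = c(-10, 10))
  expect_equal(f$scale_c, 2, tolerance = 1e-9)
  expect_equal(f$background, 5, tolerance = 1e-8)
  expect_lt(f$chi2_reduced, 1e-15)
  # active bound pins the constant
  f2 <- fit_to_data(th, expd, background_bounds = c(0, 0.1))
  expect_equal(f2$background, 0.1)
  expect_gt(f2$chi2_reduced, f$chi2_reduced)
  # degenerate theory
  flat <- saxs_curve(s, rep(3, length(s)))
  expect_error(fit_to_data(flat, expd), "degenerate")
  # missing errors fall back to unit weights with a warning
  expect_warning(fit_to_data(th, saxs_curve(s, 2 * th$I)), "unit weights")
})

test_that("chi2 is near 1 for correctly specified noise (distributional)", {
  m <- random_bead_model(80, envelope_radius = 25, seed = 5)
  s <- seq(0.005, 0.3, length.out = 500)
  th <- debye_intensity(m, s, form_factor = "gaussian_sphere")
  set.seed(77)
  chis <- vapply(1:50, function(k) {
    noisy <- apply_noise(saxs_curve(s, th$I), noise_model(0.01))
    fit_to_data(th, noisy, background_bounds = c(0, 0))$chi2_reduced
  }, numeric(1))
  expect_gt(mean(chis), 0.7)
  expect_lt(mean(chis), 1.3)
})

test_that("sparse-grid search matches the full-grid optimum on clean data", {
  m <- random_bead_model(60, envelope_radius = 25, seed = 6)
  s <- seq(0.005, 0.3, length.out = 1500)
  th <- debye_intensity(m, s, form_factor = "gaussian_sphere")
  expd <- saxs_curve(s, 1.7 * th$I + 2, sigma = 0.01 * th$I + 1e-6)
  f_sparse <- fit_to_data(th, expd, background_bounds = c(-5, 5),
                          max_points = 128L)
  f_full <- fit_to_data(th, expd, background_bounds = c(-5, 5),
                        max_points = length(s))
  expect_equal(f_sparse$scale_c, f_full$scale_c, tolerance = 0.01)
  expect_equal(f_sparse$background, f_full$background, tolerance = 0.05)
})
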