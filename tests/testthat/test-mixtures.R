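make_pair <- function(seed = 3, n_grid = 150) {
  mono <- random_bead_model(100, envelope_radius = 25, seed = seed)
  dimer <- dimerize(mono)
  s <- seq(0.005, 0.3, length.out = n_grid)
  ff <- build_formfactors(list(mono, dimer), s_grid = s,
                          labels = c("monomer", "dimer"))
  list(mono = mono, dimer = dimer, s = s, ff = ff)
}

test_that("form-factor assembly combines curves and models on one grid", {
  px <- make_pair()
  expect_equal(ncol(px$ff$components), 2L)
  expect_equal(px$ff$components[, 2][1],
               debye_intensity(px$dimer, px$s)$I[1])
  # curve sources on identical grids pass through unchanged
  c1 <- saxs_curve(px$s, px$ff$components[, 1])
  c2 <- saxs_curve(px$s, px$ff$components[, 2])
  ff2 <- build_formfactors(list(c1, c2))
  expect_equal(ff2$components, px$ff$components, tolerance = 1e-12)
  # a list of models (NMR-ensemble style) expands to one component each
  mods <- list(random_bead_model(20, seed = 1),
               random_bead_model(20, seed = 2),
               random_bead_model(20, seed = 3))
  ff3 <- build_formfactors(list(mods), s_grid = px$s)
  expect_equal(ncol(ff3$components), 3L)
  # disjoint ranges fail
  d1 <- saxs_curve(c(0.01, 0.02, 0.03), c(3, 2, 1))
  d2 <- saxs_curve(c(0.2, 0.3, 0.4), c(3, 2, 1))
  expect_error(build_formfactors(list(d1, d2)), "disjoint")
})

test_that("form-factor files round-trip", {
  px <- make_pair()
  f <- tempfile(fileext = ".dat")
  write_formfactors(px$ff, f)
  back <- read_formfactors(f)
  expect_equal(back$components, unname(px$ff$components), tolerance = 1e-7)
  expect_equal(back$labels, px$ff$labels)
})

test_that("noiseless mixtures are decomposed exactly", {
  px <- make_pair()
  mix <- saxs_curve(px$s, 0.3 * px$ff$components[, 1] +
                      0.7 * px$ff$components[, 2])
  fit <- fit_fractions(px$ff, mix)
  expect_equal(fit$fractions, c(0.3, 0.7), tolerance = 1e-8)
  expect_lt(fit$chi2_reduced, 1e-15)
  pure <- saxs_curve(px$s, px$ff$components[, 1])
  fit_pure <- fit_fractions(px$ff, pure)
  expect_equal(fit_pure$fractions, c(1, 0), tolerance = 1e-8)
})

test_that("fractions are invariant to rescaling the data", {
  px <- make_pair()
  mix <- saxs_curve(px$s, 0.4 * px$ff$components[, 1] +
                      0.6 * px$ff$components[, 2],
                    sigma = 0.01 * (0.4 * px$ff$components[, 1] +
                                      0.6 * px$ff$components[, 2]))
  f1 <- fit_fractions(px$ff, mix)
  f2 <- fit_fractions(px$ff, curve_scale(mix, 12.5))
  expect_equal(f1$fractions, f2$fractions, tolerance = 1e-9)
  expect_equal(f2$overall_scale, 12.5 * f1$overall_scale, tolerance = 1e-6)
})

test_that("duplicated components split weight but conserve the total", {
  px <- make_pair()
  ff3 <- px$ff
  ff3$components <- cbind(ff3$components, ff3$components[, 2])
  ff3$labels <- c(ff3$labels, "dimer-copy")
  mix <- saxs_curve(px$s, 0.3 * px$ff$components[, 1] +
                      0.7 * px$ff$components[, 2])
  fit <- fit_fractions(ff3, mix)
  expect_equal(fit$fractions[1], 0.3, tolerance = 1e-4)
  expect_equal(fit$fractions[2] + fit$fractions[3], 0.7, tolerance = 1e-4)
})

test_that("fixed fractions constrain the solution", {
  px <- make_pair()
  mix <- saxs_curve(px$s, 0.3 * px$ff$components[, 1] +
                      0.7 * px$ff$components[, 2])
  fit <- fit_fractions(px$ff, mix, fixed = c(monomer = 0.3))
  expect_true(fit$fixed_mask[1])
  expect_equal(fit$fractions, c(0.3, 0.7), tolerance = 1e-8)
  # fixing a wrong value degrades the fit but keeps the constraint
  fit_wrong <- fit_fractions(px$ff, mix, fixed = c(monomer = 0.6))
  expect_equal(fit_wrong$fractions[1], 0.6)
  expect_gt(fit_wrong$chi2_reduced, fit$chi2_reduced)
  expect_error(fit_fractions(px$ff, mix, fixed = c(monomer = 1.2)), "< 1")
})

test_that("mixture recovery under noise reaches the expected accuracy", {
  px <- make_pair()
  set.seed(42)
  errs <- vapply(1:20, function(k) {
    v <- runif(1, 0.2, 0.8)
    clean <- v * px$ff$components[, 1] + (1 - v) * px$ff$components[, 2]
    noisy <- apply_noise(saxs_curve(px$s, clean), noise_model(0.02))
    fit <- fit_fractions(px$ff, noisy)
    abs(fit$fractions[1] - v)
  }, numeric(1))
  expect_lte(mean(errs), 0.15)
})

test_that("two-state decomposition recovers assembly/subcomplex fractions", {
  px <- make_pair()
  sub_curve <- debye_intensity(
    bead_model(px$dimer$coords[px$dimer$chain_id == "A", , drop = FALSE]),
    px$s)
  full_curve <- debye_intensity(px$dimer, px$s)
  mix <- saxs_curve(px$s, 0.5 * full_curve$I + 0.5 * sub_curve$I)
  fit <- two_state_decompose(px$dimer, "A", mix)
  expect_equal(fit$fractions, c(0.5, 0.5), tolerance = 1e-8)
  # data from the full assembly only
  pure <- saxs_curve(px$s, full_curve$I)
  fit0 <- two_state_decompose(px$dimer, "A", pure)
  expect_lt(fit0$fractions[2], 1e-8)
  expect_error(two_state_decompose(px$dimer, "Z", pure), "empty")
})

test_that("recovery error inflates outside the reliable fraction window", {
  px <- make_pair()
  set.seed(7)
  err_at <- function(v, reps = 5) {
    mean(vapply(seq_len(reps), function(k) {
      clean <- v * px$ff$components[, 1] + (1 - v) * px$ff$components[, 2]
      noisy <- apply_noise(saxs_curve(px$s, clean), noise_model(0.05))
      abs(fit_fractions(px$ff, noisy)$fractions[1] - v)
    }, numeric(1)))
  }
  inside <- mean(c(err_at(0.35), err_at(0.5), err_at(0.65)))
  outside <- mean(c(err_at(0.05), err_at(0.95)))
  # relative error of the minor species degrades at the extremes
  rel_inside <- inside / 0.5
  rel_outside <- outside / 0.05
  expect_gt(rel_outside, rel_inside)
})
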