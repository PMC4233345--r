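test_that("autorg recovers exact Guinier parameters on ideal data", {
  cur <- guinier_curve(rg = 20, i0 = 1000)
  g <- autorg(cur)
  expect_equal(g$rg, 20, tolerance = 1e-6)
  expect_equal(g$i0, 1000, tolerance = 1e-6)
  expect_lte(g$srg_max, 1.3)
  expect_lt(g$first_point, g$last_point)
})

test_that("autorg is accurate under noise (Monte-Carlo) and scale-equivariant", {
  cur <- guinier_curve(rg = 20, i0 = 1000)
  # for the equivariance check keep s*Rg strictly inside the admissible
  # limit so no window sits on the acceptance boundary
  cur_eq <- guinier_curve(rg = 20, i0 = 1000, s_max = 1.25 / 20)
  set.seed(11)
  rgs <- vapply(1:50, function(k) {
    noisy <- apply_noise(cur, noise_model(relative = 0.01))
    autorg(noisy)$rg
  }, numeric(1))
  expect_lt(abs(mean(rgs) - 20) / 20, 0.02)
  # scale equivariance
  g1 <- autorg(cur_eq)
  g2 <- autorg(curve_scale(cur_eq, 37.5))
  expect_equal(g2$rg, g1$rg)
  expect_equal(c(g2$first_point, g2$last_point),
               c(g1$first_point, g1$last_point))
  expect_equal(g2$i0, 37.5 * g1$i0, tolerance = 1e-9)
})

test_that("autorg rejects curves without a Guinier region", {
  s <- seq(0.005, 0.06, length.out = 60)
  rising <- saxs_curve(s, 100 * (1 + 40 * s))  # aggregation mimic
  expect_error(autorg(rising), "Guinier")
})

test_that("curve arithmetic propagates errors in quadrature", {
  cur <- guinier_curve(sigma_rel = 0.02)
  z <- curve_subtract(cur, cur)
  expect_true(all(z$I == 0))
  expect_equal(z$sigma, sqrt(2) * cur$sigma, tolerance = 1e-12)
  sc <- curve_scale(cur, 2.5)
  expect_equal(sc$I, 2.5 * cur$I)
  expect_equal(sc$sigma, 2.5 * cur$sigma)
  other <- guinier_curve(rg = 35, sigma_rel = 0.02)
  other$s <- other$s + 1e-4  # incompatible grid
  expect_error(curve_subtract(cur, other), "grid")
})

test_that("averaging identical curves keeps I and shrinks sigma as 1/sqrt(n)", {
  cur <- guinier_curve(sigma_rel = 0.02)
  for (n in c(2L, 4L)) {
    avg <- curve_average(rep(list(cur), n))
    expect_equal(avg$I, cur$I, tolerance = 1e-12)
    expect_equal(avg$sigma, cur$sigma / sqrt(n), tolerance = 1e-12)
  }
})

test_that("curve_compare recovers scales and is symmetric in p-value", {
  cur <- guinier_curve(sigma_rel = 0.01)
  same <- curve_compare(cur, cur)
  expect_equal(same$chi2_reduced, 0, tolerance = 1e-12)
  expect_equal(same$scale_applied, 1, tolerance = 1e-6)
  tripled <- curve_scale(cur, 3)
  cmp <- curve_compare(cur, tripled)
  expect_equal(cmp$scale_applied, 1 / 3, tolerance = 1e-6)
  expect_equal(cmp$chi2_reduced, 0, tolerance = 1e-10)
  # p-value symmetry
  set.seed(21)
  a <- apply_noise(cur, noise_model(0.02))
  b <- apply_noise(cur, noise_model(0.02))
  expect_equal(curve_compare(a, b)$p_value, curve_compare(b, a)$p_value,
               tolerance = 0.02)
})

test_that("curve_compare chi2 is distributed around 1 for matched noise", {
  cur <- guinier_curve(n = 200, sigma_rel = NULL)
  set.seed(31)
  chis <- vapply(1:100, function(k) {
    a <- apply_noise(cur, noise_model(0.02))
    b <- apply_noise(cur, noise_model(0.02))
    curve_compare(a, b)$chi2_reduced
  }, numeric(1))
  expect_lt(abs(mean(chis) - 1), 3 / sqrt(200))
})

test_that("merging recovers a common model across two half-range curves", {
  s_full <- seq(0.01, 0.40, length.out = 400)
  model <- analytic_curve("guinier", s_grid = s_full, rg = 15, i0 = 500)
  low <- saxs_curve(s_full[s_full <= 0.15], model$I[s_full <= 0.15],
                    sigma = 0.01 * model$I[s_full <= 0.15])
  hi_idx <- s_full >= 0.10
  high <- saxs_curve(s_full[hi_idx], 2 * model$I[hi_idx],
                     sigma = 0.02 * model$I[hi_idx])
  merged <- curve_merge(low, high)
  ref <- approx(model$s, model$I, merged$s)$y
  expect_lt(max(abs(merged$I - ref) / ref), 1e-6)
  # self-merge keeps the profile
  self <- curve_merge(low, low)
  expect_equal(self$s, low$s)
  expect_equal(self$I, low$I, tolerance = 1e-10)
  # disjoint ranges fail
  lo2 <- saxs_curve(c(0.01, 0.02, 0.03), c(3, 2, 1))
  hi2 <- saxs_curve(c(0.2, 0.3, 0.4), c(3, 2, 1))
  expect_error(curve_merge(lo2, hi2), "disjoint")
})
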