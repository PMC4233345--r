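make_pool <- function(m = 50, n_grid = 80, seed = 1) {
  set.seed(seed)
  s <- seq(0.01, 0.3, length.out = n_grid)
  models <- lapply(seq_len(m), function(k) {
    random_bead_model(40, envelope_radius = runif(1, 12, 45),
                      seed = 100 + k)
  })
  curves <- lapply(models, function(mo) debye_intensity(mo, s))
  list(pool = curve_pool(curves, rg = vapply(models, model_rg, numeric(1))),
       curves = curves, s = s)
}

test_that("a planted 3-member ensemble is recovered from a 50-member pool", {
  px <- make_pool()
  truth <- c(7, 20, 33)
  expI <- rowMeans(vapply(truth, function(i) px$curves[[i]]$I,
                          numeric(length(px$s))))
  expc <- saxs_curve(px$s, expI, sigma = 0.01 * expI)
  sol <- select_ensemble(px$pool, expc, seed = 3, n_restarts = 10L)
  expect_lt(sol$chi2_reduced, 0.01)
  # the true members dominate selection frequency across seeds
  freq <- integer(50)
  for (sd in 1:10) {
    sel <- unique(select_ensemble(px$pool, expc, seed = sd)$members)
    freq[sel] <- freq[sel] + 1L
  }
  expect_true(all(freq[truth] >= sort(freq[-truth], decreasing = TRUE)[1]))
})

test_that("selection is bit-reproducible for a fixed seed", {
  px <- make_pool()
  expI <- rowMeans(vapply(c(5, 25), function(i) px$curves[[i]]$I,
                          numeric(length(px$s))))
  expc <- saxs_curve(px$s, expI, sigma = 0.01 * expI)
  s1 <- select_ensemble(px$pool, expc, seed = 11, n_restarts = 2L)
  s2 <- select_ensemble(px$pool, expc, seed = 11, n_restarts = 2L)
  expect_identical(s1$members, s2$members)
  expect_identical(s1$chi2_reduced, s2$chi2_reduced)
})

test_that("the GA beats the best random chromosome of comparable budget", {
  px <- make_pool()
  expI <- rowMeans(vapply(c(10, 40), function(i) px$curves[[i]]$I,
                          numeric(length(px$s))))
  expc <- saxs_curve(px$s, expI, sigma = 0.01 * expI)
  sol <- select_ensemble(px$pool, expc, seed = 2, n_restarts = 2L)
  # evaluate 100 random chromosomes with the same fitness definition
  set.seed(2)
  wts <- 1 / expc$sigma^2
  rand_chi <- vapply(1:100, function(k) {
    ch <- sample.int(50, sample(5:50, 1), replace = TRUE)
    avg <- rowMeans(px$pool$I[, ch, drop = FALSE])
    p <- saskit:::fit_scale_background(avg, expc$I, wts, 0, 0)
    sum(wts * (expc$I - p[1] * avg - p[2])^2) / (length(px$s) - 1)
  }, numeric(1))
  expect_lte(sol$chi2_reduced, min(rand_chi))
})

test_that("rigid systems give narrow selected Rg distributions", {
  px <- make_pool()
  compact <- which.min(px$pool$rg)
  expc <- saxs_curve(px$s, px$curves[[compact]]$I,
                     sigma = 0.01 * px$curves[[compact]]$I)
  sol <- select_ensemble(px$pool, expc, seed = 4)
  rep <- flexibility_report(sol)
  expect_lt(rep$variance_ratio, 0.3)
  expect_equal(rep$verdict, "rigid")
})

test_that("flexible systems keep the pool-wide Rg spread", {
  px <- make_pool()
  expI <- rowMeans(px$pool$I)  # the whole pool contributes
  expc <- saxs_curve(px$s, expI, sigma = 0.01 * expI)
  sol <- select_ensemble(px$pool, expc, seed = 5)
  rep <- flexibility_report(sol)
  expect_lt(sol$chi2_reduced, 1)
  expect_gt(rep$variance_ratio, 0.3)
})

test_that("verdicts behave on constructed distributions", {
  sol <- structure(list(rg_selected = c(20, 25, 30, 35, 40),
                        rg_pool = c(20, 25, 30, 35, 40)),
                   class = "ensemble_solution")
  rep <- flexibility_report(sol)
  expect_equal(rep$variance_ratio, 1)
  expect_equal(rep$verdict, "flexible")
  sol2 <- structure(list(rg_selected = rep(25, 6),
                         rg_pool = c(20, 25, 30, 35, 40)),
                    class = "ensemble_solution")
  rep2 <- flexibility_report(sol2)
  expect_equal(rep2$variance_ratio, 0)
  expect_equal(rep2$verdict, "rigid")
  # degenerate pool: identical members
  sol3 <- structure(list(rg_selected = rep(25, 4), rg_pool = rep(25, 9)),
                    class = "ensemble_solution")
  expect_equal(flexibility_report(sol3)$verdict, "indeterminate")
  # bimodal selection sits between the verdict bands
  sol4 <- structure(list(rg_selected = c(26, 26, 34, 34),
                         rg_pool = seq(20, 40, length.out = 15)),
                    class = "ensemble_solution")
  rep4 <- flexibility_report(sol4)
  expect_equal(rep4$verdict, "indeterminate")
})

test_that("degenerate pools of identical curves are indeterminate", {
  s <- seq(0.01, 0.3, length.out = 60)
  cu <- analytic_curve("guinier", s_grid = s, rg = 25, i0 = 100)
  pool <- curve_pool(rep(list(cu), 12), rg = rep(25, 12))
  expc <- saxs_curve(s, cu$I, sigma = 0.01 * cu$I)
  sol <- select_ensemble(pool, expc, seed = 1, n_restarts = 1L)
  expect_lt(sol$chi2_reduced, 1e-10)
  expect_equal(flexibility_report(sol)$verdict, "indeterminate")
})
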