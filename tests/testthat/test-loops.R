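test_that("grown traces satisfy all geometry invariants", {
  tr2 <- grow_loop(2)
  expect_equal(end_to_end(tr2), 3.8, tolerance = 1e-9)
  set.seed(1)
  for (k in 1:10) {
    tr <- grow_loop(30)
    expect_true(validate_trace(tr))
  }
  expect_error(grow_loop(1), "n_residues")
  expect_error(grow_loop(101), "n_residues")
})

test_that("end-to-end distances stay below the contour length and spread widely", {
  set.seed(3)
  d <- vapply(1:200, function(k) end_to_end(grow_loop(30)), numeric(1))
  expect_lt(max(d), 3.8 * 29)
  expect_gt(diff(range(d)), 20)  # broad range of conformations
})

test_that("pseudo-angle mask is honoured", {
  set.seed(5)
  mask <- quasi_ramachandran_mask()
  tr <- grow_loop(20, mask = mask)
  x <- tr$coords
  for (i in 3:nrow(x)) {
    th <- saskit:::pseudo_angle(x[i - 2, ], x[i - 1, ], x[i, ])
    expect_gte(th, mask$theta_range[1] - 1e-9)
    expect_lte(th, mask$theta_range[2] + 1e-9)
    if (i >= 4) {
      gm <- saskit:::pseudo_dihedral(x[i - 3, ], x[i - 2, ], x[i - 1, ],
                                     x[i, ])
      fz <- mask$forbidden
      inside <- th >= fz$theta[1] && th <= fz$theta[2] &&
        gm >= fz$gamma[1] && gm <= fz$gamma[2]
      expect_false(inside)
    }
  }
})

test_that("library bins are tiled at the discretisation width and filled exactly", {
  lib <- build_library(lengths = 10L, per_bin = 5L, pool_per_length = 200L,
                       seed = 2)
  bins <- lib$bins[["10"]]
  expect_gt(length(bins), 0L)
  centres <- as.numeric(names(bins))
  expect_true(all(abs(centres %% 2 - 1) < 1e-9))  # odd multiples of 1 A
  expect_true(all(centres < 3.8 * 9))
  for (ctr in names(bins)) {
    expect_length(bins[[ctr]], 5L)
    for (tr in bins[[ctr]]) {
      expect_true(validate_trace(tr))
      expect_lt(abs(end_to_end(tr) - as.numeric(ctr)), 1)
    }
  }
  # stored traces are mutually distinct
  ctr <- names(bins)[1]
  prs <- combn(length(bins[[ctr]]), 2)
  for (k in seq_len(ncol(prs))) {
    r <- saskit:::kabsch_rmsd(bins[[ctr]][[prs[1, k]]]$coords,
                              bins[[ctr]][[prs[2, k]]]$coords)
    expect_gt(r, 0.5)
  }
})

test_that("library generation is reproducible for a fixed seed", {
  lib1 <- build_library(lengths = 8L, per_bin = 3L, pool_per_length = 60L,
                        seed = 9)
  lib2 <- build_library(lengths = 8L, per_bin = 3L, pool_per_length = 60L,
                        seed = 9)
  expect_identical(lib1$bins, lib2$bins)
})

test_that("anchored linker queries place traces rigidly", {
  lib <- build_library(lengths = 10L, per_bin = 5L, pool_per_length = 200L,
                       seed = 4)
  ctr <- as.numeric(names(lib$bins[["10"]])[1])
  set.seed(6)
  for (k in 1:20) {
    dir <- saskit:::random_unit_vectors(1)[1, ]
    a <- runif(3, -20, 20)
    b <- a + ctr * dir
    tr <- query_linker(lib, 10L, a, b)
    expect_false(is.null(tr))
    # endpoint 1 coincides with the anchor
    expect_lt(sqrt(sum((tr$coords[1, ] - a)^2)), 1e-9)
    # end-to-end direction points at anchor b
    v <- tr$coords[10, ] - tr$coords[1, ]
    expect_lt(sum(abs(v / sqrt(sum(v^2)) - dir)), 1e-6)
    # internal geometry is preserved bit-for-bit up to rotation: bonds exact
    expect_true(validate_trace(tr, tol = 1e-6))
  }
  # beyond the contour length: rejection signal, not an error
  expect_null(query_linker(lib, 10L, c(0, 0, 0), c(500, 0, 0)))
  expect_error(query_linker(lib, 55L, c(0, 0, 0), c(10, 0, 0)), "absent")
})

test_that("rigid placement preserves all internal pairwise distances", {
  lib <- build_library(lengths = 12L, per_bin = 3L, pool_per_length = 100L,
                       seed = 5)
  ctr <- as.numeric(names(lib$bins[["12"]])[1])
  set.seed(8)
  tr <- query_linker(lib, 12L, c(3, 4, 5), c(3 + ctr, 4, 5))
  d_placed <- dist(tr$coords)
  # compare against the stored trace with the same end-to-end distance
  stored <- lib$bins[["12"]]
  match_found <- FALSE
  for (bin in stored) for (cand in bin) {
    if (max(abs(dist(cand$coords) - d_placed)) < 1e-9 * max(d_placed)) {
      match_found <- TRUE
    }
  }
  expect_true(match_found)
})
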