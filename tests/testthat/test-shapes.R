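test_that("NSD is zero on identity, symmetric, and matches brute force", {
  m <- random_bead_model(30, seed = 2)
  expect_lt(nsd(m, m), 1e-7)
  # two unit cubes of 8 beads offset by 10 A
  cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  cube2 <- cube
  cube2[, 1] <- cube2[, 1] + 10
  expect_equal(nsd(cube, cube2), nsd_bruteforce(cube, cube2),
               tolerance = 1e-12)
  a <- random_bead_model(25, seed = 3)
  b <- random_bead_model(35, seed = 4)
  expect_equal(nsd(a, b), nsd(b, a), tolerance = 1e-12)
  expect_equal(nsd(a, b), nsd_bruteforce(a$coords, b$coords),
               tolerance = 1e-12)
  expect_error(nsd(matrix(0, 1, 3), cube), "single")
})

test_that("NSD is invariant when both models move rigidly together", {
  a <- random_bead_model(25, seed = 3)
  b <- random_bead_model(35, seed = 4)
  ref <- nsd(a, b)
  rot <- random_rotation(5)
  shift <- c(3, -8, 11)
  a2 <- sweep(a$coords %*% t(rot), 2, shift, `+`)
  b2 <- sweep(b$coords %*% t(rot), 2, shift, `+`)
  expect_lt(abs(nsd(a2, b2) - ref), 1e-10)
})

test_that("P1 superposition recovers planted rigid transforms", {
  a <- random_bead_model(60, envelope_radius = 20, seed = 11)
  rot <- random_rotation(7)
  b <- bead_model(sweep(a$coords %*% t(rot), 2, c(12, -5, 3), `+`))
  sp <- superpose(a, b)
  expect_lt(sp$nsd_min, 1e-3)
  # recovered transform maps b back onto a
  expect_lt(max(abs(sp$transformed - a$coords)), 0.5)
  # self-superposition is identity-equivalent
  sps <- superpose(a, a)
  expect_lt(sps$nsd_min, 1e-6)
})

test_that("enantiomer testing resolves mirror images", {
  a <- random_bead_model(40, envelope_radius = 18, seed = 13)
  m <- a$coords
  m[, 3] <- -m[, 3]
  b <- bead_model(m)
  off <- superpose(a, b, enantiomers = FALSE)
  on <- superpose(a, b, enantiomers = TRUE)
  expect_lt(on$nsd_min, 1e-3)
  expect_gt(off$nsd_min, 10 * on$nsd_min)
  expect_true(on$mirrored)
})

test_that("Pn superposition recovers rotations modulo the symmetry order", {
  tri <- dimerize(random_bead_model(30, envelope_radius = 12, seed = 5),
                  n_fold = 3, offset = 15)
  rot40 <- saskit:::rotation_about_axis(c(0, 0, 1), 40 * pi / 180)
  moved <- bead_model(tri$coords %*% t(rot40))
  sp <- superpose(tri, moved, symmetry = "Pn")
  expect_lt(sp$nsd_min, 1e-3)
  ang <- atan2(sp$rotation[2, 1], sp$rotation[1, 1]) * 180 / pi
  expect_lt(min(abs(((ang + 40) %% 120)), abs(((ang + 40) %% 120) - 120)),
            0.5)
  # Pn2: axis alignment only
  shifted <- bead_model(sweep(tri$coords, 2, c(0, 0, 7), `+`))
  sp2 <- superpose(tri, shifted, symmetry = "Pn2")
  expect_lt(sp2$nsd_min, 1e-6)
  expect_equal(sp2$rotation, diag(3))
})

test_that("planted partitions are recovered with the Kelley criterion", {
  set.seed(4)
  jitter_model <- function(base, seed, sd = 0.8) {
    set.seed(seed)
    bead_model(base$coords + matrix(rnorm(3 * n_beads(base), 0, sd),
                                    ncol = 3))
  }
  a <- random_bead_model(40, envelope_radius = 18, seed = 101)
  b <- random_bead_model(40, envelope_radius = 18, seed = 202)
  # 3 copies of shape A + 3 of shape B -> k = 2, pure clusters
  six <- c(rep(list(a), 3), rep(list(b), 3))
  cl6 <- cluster_models(six, metric = "nsd", align_first = FALSE)
  expect_equal(cl6$k_chosen, 2L)
  expect_equal(length(unique(cl6$labels[1:3])), 1L)
  expect_equal(length(unique(cl6$labels[4:6])), 1L)
  expect_true(all(vapply(seq_along(cl6$representatives), function(g) {
    cl6$labels[cl6$representatives[g]] == g
  }, logical(1))))
  # 7 models from 3 shapes -> k = 3 (3 + 2 + 2)
  cc <- random_bead_model(40, envelope_radius = 18, seed = 303)
  seven <- c(lapply(1:3, jitter_model, base = a),
             lapply(4:5, jitter_model, base = b),
             lapply(6:7, jitter_model, base = cc))
  cl7 <- cluster_models(seven, metric = "nsd", align_first = FALSE)
  expect_equal(cl7$k_chosen, 3L)
  expect_equal(as.integer(sort(table(cl7$labels), decreasing = TRUE)),
               c(3L, 2L, 2L))
  # rmsd metric agrees for one-to-one models
  cl7r <- cluster_models(seven, metric = "rmsd")
  expect_equal(cl7r$k_chosen, 3L)
})

test_that("clustering is stable over noise seeds and permutation-invariant", {
  jitter_model <- function(base, seed, sd = 0.6) {
    set.seed(seed)
    bead_model(base$coords + matrix(rnorm(3 * n_beads(base), 0, sd),
                                    ncol = 3))
  }
  bases <- lapply(c(11, 22, 33), function(sd) {
    random_bead_model(30, envelope_radius = 16, seed = sd)
  })
  hits <- 0L
  for (rep in 1:20) {
    models <- unlist(lapply(seq_along(bases), function(g) {
      lapply(seq_len(c(3, 2, 2)[g]), function(j) {
        jitter_model(bases[[g]], seed = 1000 * rep + 10 * g + j)
      })
    }), recursive = FALSE)
    cl <- cluster_models(models, metric = "rmsd")
    if (cl$k_chosen == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 16L)  # >= 80% of runs
  # permutation invariance of the partition
  models <- unlist(lapply(seq_along(bases), function(g) {
    lapply(1:2, function(j) jitter_model(bases[[g]], seed = 10 * g + j))
  }), recursive = FALSE)
  perm <- c(4, 1, 6, 2, 5, 3)
  cl_a <- cluster_models(models, metric = "rmsd")
  cl_b <- cluster_models(models[perm], metric = "rmsd")
  same_part <- function(l1, l2) {
    all(outer(l1, l1, `==`) == outer(l2, l2, `==`))
  }
  expect_true(same_part(cl_a$labels[perm], cl_b$labels))
})

test_that("identical models short-circuit to a single cluster", {
  m <- random_bead_model(20, seed = 1)
  cl <- cluster_models(list(m, m, m), metric = "rmsd")
  expect_equal(cl$k_chosen, 1L)
})

test_that("density thresholding produces the combinatorial surface split", {
  arr <- array(0, c(7, 7, 7))
  arr[2:6, 2:6, 2:6] <- 1
  g <- density_grid(arr, voxel_size = 2)
  beads <- density_to_beads(g, 0.5, surface_cutoff = 2)
  expect_equal(n_beads(beads), 125L)
  expect_equal(sum(beads$refinable), 98L)
  expect_equal(sum(!beads$refinable), 27L)
  # single voxel above threshold
  arr1 <- array(0, c(3, 3, 3))
  arr1[2, 2, 2] <- 1
  g1 <- density_grid(arr1, voxel_size = 2, origin = c(0, 0, 0))
  b1 <- density_to_beads(g1, 0.5)
  expect_equal(n_beads(b1), 1L)
  expect_equal(b1$coords[1, ], c(2, 2, 2))
  expect_equal(b1$radius, sqrt(3 * 4) / 2)
  # monotone non-increasing bead count in the threshold
  arrr <- array(runif(125), c(5, 5, 5))
  gr <- density_grid(arrr, voxel_size = 1)
  counts <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th) {
    n_beads(density_to_beads(gr, th))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  expect_error(density_to_beads(gr, 2), "empty")
})
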