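# Shared fixtures, all generated in code.

guinier_curve <- function(rg = 20, i0 = 1000, n = 100, s_max = 1.3 / rg,
                          sigma_rel = NULL) {
  s <- seq(s_max / n, s_max, length.out = n)
  cur <- analytic_curve("guinier", s_grid = s, rg = rg, i0 = i0)
  if (!is.null(sigma_rel)) cur$sigma <- sigma_rel * cur$I
  cur
}

sphere_curve <- function(radius = 30, i0 = 1000, n = 1200, s_max = 0.40) {
  analytic_curve("sphere", s_grid = seq(0.002, s_max, length.out = n),
                 radius = radius, i0 = i0)
}

write_tmp_lines <- function(lines) {
  f <- tempfile(fileext = ".dat")
  writeLines(lines, f)
  f
}

ca_pdb_lines <- function(coords, extra_atoms = FALSE) {
  n <- nrow(coords)
  ca <- sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    seq_len(n), seq_len(n), coords[, 1], coords[, 2], coords[, 3])
  if (extra_atoms) {
    nrec <- sprintf(
      "ATOM  %5d  N   GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           N",
      n + seq_len(n), seq_len(n), coords[, 1] + 0.5, coords[, 2], coords[, 3])
    ca <- as.vector(rbind(nrec, ca))
  }
  c(ca, "END")
}

# brute-force NSD oracle: literal double loops over all pairs
nsd_bruteforce <- function(xa, xb) {
  nn_med <- function(x) {
    mins <- sapply(seq_len(nrow(x)), function(i) {
      min(sqrt(rowSums(sweep(x[-i, , drop = FALSE], 2, x[i, ])^2)))
    })
    median(mins)
  }
  da <- nn_med(xa); db <- nn_med(xb)
  t1 <- 0
  for (i in seq_len(nrow(xa))) {
    best <- Inf
    for (j in seq_len(nrow(xb))) {
      best <- min(best, sum((xa[i, ] - xb[j, ])^2))
    }
    t1 <- t1 + best
  }
  t2 <- 0
  for (j in seq_len(nrow(xb))) {
    best <- Inf
    for (i in seq_len(nrow(xa))) {
      best <- min(best, sum((xa[i, ] - xb[j, ])^2))
    }
    t2 <- t2 + best
  }
  sqrt((t1 / (nrow(xa) * db^2) + t2 / (nrow(xb) * da^2)) / 2)
}

random_rotation <- function(seed) {
  set.seed(seed)
  ang <- runif(3, -pi, pi)
  saskit:::rotation_euler(ang[1], ang[2], ang[3])
}
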