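# Multi-model analysis: the normalized spatial discrepancy (NSD),
# free and symmetry-restricted superposition, hierarchical clustering with
# the Kelley penalty for the number of clusters, and conversion of density
# grids to bead models.

# squared nearest-neighbour cross distances, a (rows) -> b
#' @noRd
cross_min_d2 <- function(a, b) {
  # ||a_i - b_j||^2 = |a_i|^2 + |b_j|^2 - 2 a_i . b_j
  aa <- rowSums(a^2); bb <- rowSums(b^2)
  d2 <- outer(aa, bb, `+`) - 2 * tcrossprod(a, b)
  pmax(d2[cbind(seq_len(nrow(d2)), max.col(-d2, ties.method = "first"))], 0)
}

#' @noRd
median_nn <- function(x) {
  if (nrow(x) < 2L) stop("model with a single point: NSD undefined", call. = FALSE)
  d <- as.matrix(stats::dist(x))
  diag(d) <- Inf
  stats::median(apply(d, 1L, min))
}

#' Normalized spatial discrepancy between two models
#'
#' \deqn{NSD^2 = \frac{1}{2}\left[\frac{1}{N_a d_b^2}\sum_{i \in a}
#'   \min_j r_{ij}^2 + \frac{1}{N_b d_a^2}\sum_{j \in b}
#'   \min_i r_{ij}^2\right]}
#' where \eqn{d_x} is the median nearest-neighbour distance within model x.
#' Evaluated at the given pose (no alignment); NSD is 0 for identical
#' models and close to 1 for similar ones.
#'
#' @param a,b \code{\link{bead_model}} objects (or n x 3 matrices) with at
#'   least 2 points each.
#' @return the NSD value.
#' @export
nsd <- function(a, b) {
  xa <- if (inherits(a, "bead_model")) a$coords else as.matrix(a)
  xb <- if (inherits(b, "bead_model")) b$coords else as.matrix(b)
  nsd_core(xa, xb, median_nn(xa), median_nn(xb))
}

# the normalisation distances are rigid-motion invariant, so pose searches
# compute them once and reuse
#' @noRd
nsd_core <- function(xa, xb, da, db) {
  t1 <- sum(cross_min_d2(xa, xb)) / (nrow(xa) * db^2)
  t2 <- sum(cross_min_d2(xb, xa)) / (nrow(xb) * da^2)
  sqrt((t1 + t2) / 2)
}

#' @noRd
apply_pose <- function(x, rot, shift) sweep(x %*% t(rot), 2L, shift, `+`)

#' Superpose model b onto model a by minimising the NSD
#'
#' \describe{
#'   \item{P1}{full search over 3 rotations + 3 translations: a
#'     deterministic orientation grid (432 poses) seeds local Nelder-Mead
#'     refinement; with \code{enantiomers = TRUE} the mirror image of b is
#'     tried as well.}
#'   \item{Pn}{both models share the z symmetry axis: only the rotation
#'     about z and the translation along z are optimised, preserving the
#'     symmetry.}
#'   \item{Pn2}{superposition reduces to aligning the symmetry axes, i.e.
#'     a centroid translation.}
#' }
#'
#' @param a,b \code{\link{bead_model}} objects.
#' @param symmetry \code{"P1"}, \code{"Pn"} or \code{"Pn2"}.
#' @param enantiomers also test the mirror image of b (P1 only).
#' @param refine_top number of best grid poses refined locally.
#' @return list with \code{nsd_min}, \code{rotation} (3 x 3),
#'   \code{translation} (length 3), \code{mirrored} flag and
#'   \code{transformed} (b's coordinates in the best pose). The transform
#'   maps b's original coordinates (after optional mirroring through the
#'   origin) as \code{x \%*\% t(rotation) + translation}.
#' @export
superpose <- function(a, b, symmetry = c("P1", "Pn", "Pn2"),
                      enantiomers = FALSE, refine_top = 3L) {
  symmetry <- match.arg(symmetry)
  xa <- a$coords; xb0 <- b$coords
  ca <- colMeans(xa)
  variants <- list(list(mirror = FALSE, x = xb0))
  if (enantiomers && symmetry == "P1") {
    xm <- xb0; xm[, 3] <- -xm[, 3]
    variants <- c(variants, list(list(mirror = TRUE, x = xm)))
  }
  best <- NULL
  for (var in variants) {
    xb <- var$x
    cb <- colMeans(xb)
    da <- median_nn(xa); db <- median_nn(xb)
    res <- switch(symmetry,
      P1 = superpose_p1(xa, xb, ca, cb, refine_top, da, db),
      Pn = superpose_pn(xa, xb, ca, cb, da, db),
      Pn2 = {
        shift <- ca - cb
        list(nsd = nsd_core(xa, sweep(xb, 2L, shift, `+`), da, db),
             rot = diag(3), shift = shift)
      })
    if (is.null(best) || res$nsd < best$nsd) {
      best <- c(res, list(mirror = var$mirror, xb = xb))
    }
  }
  transformed <- apply_pose(best$xb, best$rot, best$shift)
  list(nsd_min = best$nsd, rotation = best$rot, translation = best$shift,
       mirrored = best$mirror, transformed = transformed)
}

#' @noRd
superpose_p1 <- function(xa, xb, ca, cb, refine_top, da, db) {
  xb_c <- sweep(xb, 2L, cb)
  nsd_of <- function(par) {
    rot <- rotation_euler(par[1], par[2], par[3])
    pose <- sweep(xb_c %*% t(rot), 2L, ca + par[4:6], `+`)
    nsd_core(xa, pose, da, db)
  }
  # deterministic 432-pose orientation grid: 12 x 6 x 6 Euler combinations
  alphas <- seq(0, 2 * pi, length.out = 13L)[-13L]
  betas <- seq(0, pi, length.out = 7L)[-7L]
  gammas <- seq(0, 2 * pi, length.out = 7L)[-7L]
  grid <- expand.grid(a = alphas, b = betas, g = gammas)
  vals <- vapply(seq_len(nrow(grid)), function(i) {
    nsd_of(c(grid$a[i], grid$b[i], grid$g[i], 0, 0, 0))
  }, numeric(1))
  ord <- order(vals)[seq_len(min(refine_top, length(vals)))]
  best <- NULL
  for (i in ord) {
    start <- c(grid$a[i], grid$b[i], grid$g[i], 0, 0, 0)
    opt <- stats::optim(start, nsd_of, method = "Nelder-Mead",
                        control = list(maxit = 600L, reltol = 1e-10))
    opt <- stats::optim(opt$par, nsd_of, method = "Nelder-Mead",
                        control = list(maxit = 400L, reltol = 1e-12))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  rot <- rotation_euler(best$par[1], best$par[2], best$par[3])
  shift <- ca + best$par[4:6] - as.numeric(rot %*% cb)
  list(nsd = best$value, rot = rot, shift = shift)
}

#' @noRd
superpose_pn <- function(xa, xb, ca, cb, da, db) {
  nsd_of <- function(par) {
    rot <- rotation_about_axis(c(0, 0, 1), par[1])
    pose <- sweep(xb %*% t(rot), 2L, c(0, 0, par[2]), `+`)
    nsd_core(xa, pose, da, db)
  }
  phis <- seq(0, 2 * pi, length.out = 73L)[-73L]
  z0 <- ca[3] - cb[3]
  vals <- vapply(phis, function(p) nsd_of(c(p, z0)), numeric(1))
  start <- c(phis[which.min(vals)], z0)
  opt <- stats::optim(start, nsd_of, method = "Nelder-Mead",
                      control = list(maxit = 500L, reltol = 1e-12))
  rot <- rotation_about_axis(c(0, 0, 1), opt$par[1])
  list(nsd = opt$value, rot = rot, shift = c(0, 0, opt$par[2]))
}

#' Cluster multiple models with the Kelley criterion
#'
#' Builds the pairwise dissimilarity matrix (NSD after superposition, or
#' r.m.s.d. after Kabsch superposition for one-to-one models), merges by
#' average-linkage hierarchical clustering, and picks the number of
#' clusters with the Kelley penalty: for each candidate k the average
#' spread (mean over clusters with at least 2 members of the mean
#' intra-cluster distance) is normalised linearly onto [1, N - 1] across
#' k, and \code{penalty(k) = normalised spread + k} is minimised, ties
#' going to the smaller k. Each cluster's representative is the member
#' with the lowest mean distance to its cluster mates; models whose mean
#' distance to all others exceeds mean + 2 SD are flagged (never
#' discarded).
#'
#' @param models list of \code{\link{bead_model}} objects (>= 3).
#' @param metric \code{"nsd"} or \code{"rmsd"} (the latter requires equal
#'   point counts with one-to-one correspondence).
#' @param align_first superpose every pair before evaluating the NSD.
#' @param ... passed to \code{\link{superpose}}.
#' @return a \code{cluster_result}: list with \code{labels},
#'   \code{k_chosen}, \code{penalty} (per candidate k),
#'   \code{representatives}, \code{distance_matrix}, \code{outlier_flag}
#'   and the \code{hclust} tree.
#' @export
cluster_models <- function(models, metric = c("nsd", "rmsd"),
                           align_first = TRUE, ...) {
  metric <- match.arg(metric)
  n <- length(models)
  stopifnot(n >= 3L)
  dm <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dm[i, j] <- dm[j, i] <- if (metric == "rmsd") {
        kabsch_rmsd(models[[i]]$coords, models[[j]]$coords)
      } else if (align_first) {
        superpose(models[[i]], models[[j]], ...)$nsd_min
      } else {
        nsd(models[[i]], models[[j]])
      }
    }
  }
  if (max(dm) < 1e-9) {
    return(structure(list(labels = rep(1L, n), k_chosen = 1L,
                          penalty = NULL, representatives = 1L,
                          distance_matrix = dm,
                          outlier_flag = rep(FALSE, n), tree = NULL),
                     class = "cluster_result"))
  }
  tree <- stats::hclust(stats::as.dist(dm), method = "average")
  ks <- 2:(n - 1L)
  spread_of <- function(labels) {
    sp <- vapply(split(seq_len(n), labels), function(members) {
      if (length(members) < 2L) return(NA_real_)
      mean(dm[members, members][upper.tri(matrix(0, length(members),
                                                 length(members)))])
    }, numeric(1))
    if (all(is.na(sp))) 0 else mean(sp, na.rm = TRUE)
  }
  spreads <- vapply(ks, function(k) spread_of(stats::cutree(tree, k)),
                    numeric(1))
  rng <- range(spreads)
  # spread profiles that are flat to numerical precision carry no cluster
  # signal; stretching them onto [1, N-1] would amplify float noise, so
  # they collapse to a constant and parsimony (the +k term) decides
  norm <- if (diff(rng) > 1e-6 * max(dm)) {
    (spreads - rng[1]) / diff(rng) * (n - 2L) + 1
  } else rep(1, length(spreads))
  penalty <- norm + ks
  k_chosen <- ks[which.min(penalty)]   # which.min takes the first = smaller k
  labels <- stats::cutree(tree, k_chosen)
  representatives <- vapply(split(seq_len(n), labels), function(members) {
    if (length(members) == 1L) return(members)
    members[which.min(rowMeans(dm[members, members, drop = FALSE]))]
  }, integer(1))
  mean_d <- rowMeans(dm) * n / (n - 1L)
  outlier_flag <- mean_d > mean(mean_d) + 2 * stats::sd(mean_d)
  structure(list(labels = labels, k_chosen = k_chosen,
                 penalty = stats::setNames(penalty, ks),
                 representatives = representatives,
                 distance_matrix = dm, outlier_flag = outlier_flag,
                 tree = tree),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("cluster_result:", length(x$labels), "models in", x$k_chosen,
      "cluster(s); sizes:",
      paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Convert a density grid to a bead model
#'
#' One bead is placed at the centre of every voxel with value at or above
#' the threshold, with radius half the voxel diagonal. With
#' \code{surface_cutoff} set, beads within that distance (Angstrom) of the
#' thresholded boundary are marked refinable while core beads are fixed,
#' yielding a search volume whose surface may change phase during
#' downstream refinement.
#'
#' @param grid a \code{\link{density_grid}}.
#' @param threshold density value defining the particle.
#' @param surface_cutoff optional distance (Angstrom) from the boundary
#'   within which beads are refinable.
#' @return a \code{\link{bead_model}} with the \code{refinable} flag set.
#' @export
density_to_beads <- function(grid, threshold, surface_cutoff = NULL) {
  stopifnot(inherits(grid, "density_grid"))
  inside <- grid$values >= threshold
  if (!any(inside)) stop("nothing above threshold: empty model", call. = FALSE)
  idx <- which(inside, arr.ind = TRUE)
  coords <- sweep((idx - 1), 2L, grid$voxel_size, `*`)
  coords <- sweep(coords, 2L, grid$origin, `+`)
  radius <- sqrt(sum(grid$voxel_size^2)) / 2
  refinable <- rep(TRUE, nrow(idx))
  if (!is.null(surface_cutoff)) {
    d <- dim(grid$values)
    cutoff_vox <- surface_cutoff / grid$voxel_size
    # a bead is surface when any voxel within the cutoff (per-axis voxel
    # offsets with Euclidean norm <= cutoff) lies outside the particle
    offs <- expand.grid(dx = -ceiling(cutoff_vox[1]):ceiling(cutoff_vox[1]),
                        dy = -ceiling(cutoff_vox[2]):ceiling(cutoff_vox[2]),
                        dz = -ceiling(cutoff_vox[3]):ceiling(cutoff_vox[3]))
    dist_a <- sqrt((offs$dx * grid$voxel_size[1])^2 +
                     (offs$dy * grid$voxel_size[2])^2 +
                     (offs$dz * grid$voxel_size[3])^2)
    offs <- offs[dist_a <= surface_cutoff + 1e-9 & dist_a > 0, , drop = FALSE]
    refinable <- vapply(seq_len(nrow(idx)), function(r) {
      i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
      ii <- i + offs$dx; jj <- j + offs$dy; kk <- k + offs$dz
      out_of_grid <- ii < 1 | ii > d[1] | jj < 1 | jj > d[2] |
        kk < 1 | kk > d[3]
      if (any(out_of_grid)) return(TRUE)
      any(!inside[cbind(ii, jj, kk)])
    }, logical(1))
  }
  bead_model(coords, weight = 1, radius = radius,
             refinable = refinable, label = "density-derived beads")
}
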