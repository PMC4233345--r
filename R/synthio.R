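# Synthetic-data generation: analytic body form factors, random bead
# models, noisy concentration series and mixtures. Every generator is
# deterministic for a fixed seed.

#' Analytic scattering curve of a simple body
#'
#' \describe{
#'   \item{sphere}{\eqn{I(s) = I_0 [3 (\sin sR - sR \cos sR)/(sR)^3]^2}.}
#'   \item{ellipsoid}{triaxial ellipsoid with semi-axes (a, b, c),
#'     orientationally averaged by Gauss-Legendre quadrature over the
#'     direction octant (order \code{n_quad} per dimension; doubling the
#'     order changes the result by < 0.1 percent over the usual s-range).}
#'   \item{guinier}{the exact exponential law
#'     \eqn{I(s) = I_0 \exp(-s^2 R_g^2 / 3)}.}
#' }
#'
#' @param body one of \code{"sphere"}, \code{"ellipsoid"}, \code{"guinier"}.
#' @param s_grid momentum-transfer grid (Angstrom^-1).
#' @param radius sphere radius (Angstrom).
#' @param semi_axes ellipsoid semi-axes, numeric length 3 (Angstrom).
#' @param rg,i0 Guinier parameters; \code{i0} scales every body.
#' @param n_quad Gauss-Legendre order per dimension for the ellipsoid.
#' @return a \code{\link{saxs_curve}} without uncertainties.
#' @export
analytic_curve <- function(body = c("sphere", "ellipsoid", "guinier"),
                           s_grid, radius = 30, semi_axes = c(20, 20, 60),
                           rg = 20, i0 = 1, n_quad = 64) {
  body <- match.arg(body)
  s <- as.numeric(s_grid)
  I <- switch(body,
    sphere = i0 * sphere_ff(s, radius)^2,
    guinier = i0 * exp(-s^2 * rg^2 / 3),
    ellipsoid = {
      stopifnot(all(semi_axes > 0))
      gl <- pracma::gaussLegendre(n_quad, 0, 1)       # u = cos(theta)
      gp <- pracma::gaussLegendre(n_quad, 0, pi / 2)  # phi over one octant
      a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
      acc <- numeric(length(s))
      for (iu in seq_len(n_quad)) {
        u <- gl$x[iu]
        st <- sqrt(1 - u^2)
        reff <- sqrt((a * st * cos(gp$x))^2 + (b * st * sin(gp$x))^2 +
                       (cc * u)^2)
        wts <- gl$w[iu] * gp$w
        for (ip in seq_len(n_quad)) {
          acc <- acc + wts[ip] * sphere_ff(s, reff[ip])^2
        }
      }
      i0 * acc / (pi / 2)
    })
  saxs_curve(s, I, label = paste0("analytic ", body), unit = "A")
}

# normalised sphere amplitude, ->1 as s->0
#' @noRd
sphere_ff <- function(s, R) {
  x <- s * R
  out <- rep(1, length(x))
  nz <- x > 1e-6
  out[nz] <- 3 * (sin(x[nz]) - x[nz] * cos(x[nz])) / x[nz]^3
  out
}

#' Random bead model inside a spherical envelope
#'
#' Beads are drawn uniformly inside a sphere with a minimum pairwise
#' separation (dart throwing); deterministic per seed.
#'
#' @param n number of beads (>= 2).
#' @param envelope_radius envelope sphere radius (Angstrom).
#' @param min_separation minimum pairwise distance (Angstrom).
#' @param seed RNG seed.
#' @param weight,radius passed to \code{\link{bead_model}}.
#' @return a \code{\link{bead_model}}.
#' @export
random_bead_model <- function(n, envelope_radius = 30, min_separation = 3.8,
                              seed = 1, weight = 1, radius = 1.9) {
  stopifnot(n >= 2L)
  set.seed(seed)
  coords <- matrix(NA_real_, n, 3L)
  placed <- 0L
  stall <- 0L   # draws since the last successful placement
  while (placed < n) {
    if (stall > 20000L) {
      stop("packing failure: cannot place ", n, " beads with separation ",
           min_separation, " in radius ", envelope_radius, call. = FALSE)
    }
    stall <- stall + 1L
    p <- stats::runif(3, -envelope_radius, envelope_radius)
    if (sum(p^2) > envelope_radius^2) next
    if (placed > 0L) {
      d2 <- rowSums(sweep(coords[seq_len(placed), , drop = FALSE], 2, p)^2)
      if (min(d2) < min_separation^2) next
    }
    placed <- placed + 1L
    coords[placed, ] <- p
    stall <- 0L
  }
  bead_model(coords, weight = weight, radius = radius,
             label = sprintf("random beads n=%d seed=%d", n, seed))
}

#' Build a symmetric multimer from a monomer
#'
#' Applies an n-fold rotation about the z axis (P2 for a dimer, P3 for a
#' trimer, ...) after translating the monomer off-axis so the copies do not
#' overlap.
#'
#' @param model monomer \code{\link{bead_model}}.
#' @param n_fold symmetry order (2 = dimer).
#' @param offset radial displacement of the monomer centre from the
#'   symmetry axis; defaults to the monomer Rg so the copies touch.
#' @return the multimer \code{bead_model}.
#' @export
dimerize <- function(model, n_fold = 2L, offset = NULL) {
  stopifnot(inherits(model, "bead_model"), n_fold >= 2L)
  if (is.null(offset)) offset <- max(model_rg(model), 1)
  ctr <- colMeans(model$coords)
  base <- sweep(model$coords, 2, ctr)
  base[, 1] <- base[, 1] + offset
  pieces <- lapply(seq_len(n_fold) - 1L, function(k) {
    rot <- rotation_about_axis(c(0, 0, 1), 2 * pi * k / n_fold)
    base %*% t(rot)
  })
  bead_model(do.call(rbind, pieces),
             weight = rep(model$weight, n_fold),
             radius = model$radius,
             chain_id = rep(LETTERS[seq_len(n_fold)], each = n_beads(model)),
             residue_index = rep(model$residue_index, n_fold),
             label = sprintf("%s x%d", model$label, n_fold))
}

#' Noise model for synthetic curves
#'
#' Per-point Gaussian noise with \eqn{\sigma(s) = rel \cdot |I(s)| + floor}.
#' Defaults emulate good synchrotron data: 1 percent relative error with a
#' tiny absolute floor.
#'
#' @param relative relative error fraction.
#' @param floor absolute error floor (same units as I); when \code{NULL} it
#'   is set to 1e-6 of the first intensity at application time.
#' @return an object of class \code{noise_model}.
#' @export
noise_model <- function(relative = 0.01, floor = NULL) {
  structure(list(relative = relative, floor = floor), class = "noise_model")
}

#' Apply a noise model to a curve
#'
#' @param curve a \code{\link{saxs_curve}}.
#' @param noise a \code{\link{noise_model}}.
#' @param seed RNG seed; \code{NULL} uses the current RNG state.
#' @return the noisy curve with the sigma column set to the model sigma.
#' @export
apply_noise <- function(curve, noise = noise_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fl <- noise$floor %||% (1e-6 * abs(curve$I[1]))
  sg <- noise$relative * abs(curve$I) + fl
  saxs_curve(curve$s, curve$I + stats::rnorm(length(curve$s), 0, sg), sg,
             concentration = curve$concentration,
             label = curve$label, unit = curve$unit)
}

#' Synthetic concentration series with a linear concentration effect
#'
#' Implements \eqn{I(s, c) = I_0(s) (1 - k \, c \, g(s))} with the smooth
#' low-angle weight \eqn{g(s) = \exp(-(s/s_0)^2)}, i.e. a repulsive
#' interference term proportional to concentration, plus optional Gaussian
#' noise.
#'
#' @param base infinite-dilution curve \eqn{I_0(s)}.
#' @param concentrations positive concentrations (mg/ml).
#' @param k effect strength per unit concentration;
#'   \code{k * max(c)} must stay below 1.
#' @param s0 decay scale of the low-angle weight (Angstrom^-1).
#' @param noise a \code{\link{noise_model}} or \code{NULL} for noiseless.
#' @param seed RNG seed for the noise draws.
#' @return a \code{\link{dilution_series}}; the generating truth is stored
#'   in attribute \code{"truth"}.
#' @export
noisy_series <- function(base, concentrations = c(1, 2, 4), k = 0.02,
                         s0 = 0.05, noise = noise_model(), seed = 1) {
  stopifnot(inherits(base, "saxs_curve"), all(concentrations > 0))
  if (k * max(concentrations) >= 1) {
    stop("concentration effect too strong: k * max(c) must be < 1", call. = FALSE)
  }
  g <- exp(-(base$s / s0)^2)
  set.seed(seed)
  curves <- lapply(concentrations, function(cc) {
    I <- base$I * (1 - k * cc * g)
    # curves are per-unit-concentration normalised, the form in which a
    # series enters the extrapolation
    cur <- saxs_curve(base$s, I, concentration = cc,
                      label = sprintf("c = %g", cc), unit = base$unit)
    if (!is.null(noise)) cur <- apply_noise(cur, noise)
    cur
  })
  out <- dilution_series(curves)
  attr(out, "truth") <- list(base = base, k = k, s0 = s0)
  out
}
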