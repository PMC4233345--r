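# Internal numeric helpers shared across modules.

#' @keywords internal
#' @noRd
trapz_int <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1L] - x[-n]) * (y[-1L] + y[-n])) / 2
}

# Weighted straight-line fit y = a + b x with known per-point sigma.
# Parameter covariance comes from the weight matrix alone (sigmas are
# taken at face value), so two points give an exact fit with finite errors.
#' @noRd
wls_line <- function(x, y, sigma = NULL) {
  if (is.null(sigma)) sigma <- rep(1, length(x))
  w <- 1 / sigma^2
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  if (det <= 0 || !is.finite(det)) {
    stop("degenerate design in weighted line fit", call. = FALSE)
  }
  slope <- (sw * sxy - sx * sy) / det
  intercept <- (sxx * sy - sx * sxy) / det
  slope_var <- sw / det
  intercept_var <- sxx / det
  yhat <- intercept + slope * x
  ybar <- sy / sw
  ss_tot <- sum(w * (y - ybar)^2)
  ss_res <- sum(w * (y - yhat)^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  n <- length(x)
  # two-sided p-value for slope = 0 under unit-scaled weights
  pval <- if (n > 2L && slope_var > 0) {
    tstat <- slope / sqrt(slope_var * max(ss_res / (n - 2L), .Machine$double.eps))
    2 * stats::pt(-abs(tstat), df = n - 2L)
  } else 0
  list(intercept = intercept, slope = slope,
       intercept_err = sqrt(intercept_var), slope_err = sqrt(slope_var),
       r2 = r2, p_value = pval, ss_res = ss_res, n = n)
}

# Linear interpolation of a curve onto a new grid; never extrapolates.
#' @noRd
interp_curve_values <- function(s, v, s_new) {
  if (min(s_new) < min(s) - 1e-12 || max(s_new) > max(s) + 1e-12) {
    stop("interpolation target extends beyond source s-range; extrapolation is not performed",
         call. = FALSE)
  }
  stats::approx(s, v, xout = s_new, rule = 1)$y
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Kabsch superposition of point sets (rows = points), returns rmsd.
#' @noRd
kabsch_rmsd <- function(a, b) {
  stopifnot(nrow(a) == nrow(b))
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  h <- crossprod(b0, a0)
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  br <- b0 %*% t(rot)
  sqrt(mean(rowSums((a0 - br)^2)))
}

# Uniform random unit vectors.
#' @noRd
random_unit_vectors <- function(n) {
  z <- stats::runif(n, -1, 1)
  phi <- stats::runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# Rotation matrix about arbitrary axis (Rodrigues).
#' @noRd
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  k <- matrix(c(0, -axis[3], axis[2],
                axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  diag(3) + sin(angle) * k + (1 - cos(angle)) * (k %*% k)
}

#' @noRd
rotation_euler <- function(a, b, g) {
  rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3, byrow = TRUE)
  rz2 <- matrix(c(cos(g), -sin(g), 0, sin(g), cos(g), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  rz1 %*% ry %*% rz2
}
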