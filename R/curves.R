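# Curve arithmetic, statistical comparison, averaging/merging, and the
# automatic Guinier (Rg) search.

#' Automatic Guinier analysis
#'
#' Finds the closest-to-the-origin angular interval displaying valid Guinier
#' behaviour, i.e. where \eqn{\ln I} is linear in \eqn{s^2} with negative
#' slope, and reports \eqn{R_g = \sqrt{-3 \cdot slope}} and
#' \eqn{I(0) = \exp(intercept)}.
#'
#' All contiguous windows of at least \code{min_window} points inside the
#' low-angle region are fitted by weighted least squares. Windows are
#' admissible when the slope is negative, \eqn{s R_g \le} \code{srg_limit}
#' at the window end, and the linear fit is significant. Among admissible
#' windows the one maximising
#' \code{quality = w1 * length_fraction + w2 * (1 - start_fraction) + w3 * R2}
#' is chosen, so that long windows starting close to the origin win.
#'
#' @param curve a \code{\link{saxs_curve}}.
#' @param srg_limit upper bound on \eqn{s \cdot R_g} at the window end
#'   (default 1.3, the usual globular-protein limit).
#' @param min_window minimum number of points per window.
#' @param quality_weights numeric length 3, the (length, start, R2) weights.
#' @param p_threshold reject windows whose slope p-value exceeds this.
#' @return a \code{guinier_result}: list with \code{rg}, \code{i0},
#'   \code{rg_err}, \code{i0_err}, \code{first_point}, \code{last_point}
#'   (1-based indices into the curve), \code{quality} in [0,1] and
#'   \code{srg_max}.
#' @export
#' @examples
#' cur <- analytic_curve("guinier", rg = 20, i0 = 1000,
#'                       s_grid = seq(0.005, 0.2, length.out = 120))
#' autorg(cur)
autorg <- function(curve, srg_limit = 1.3, min_window = 5L,
                   quality_weights = c(0.4, 0.3, 0.3), p_threshold = 0.05) {
  stopifnot(inherits(curve, "saxs_curve"))
  pos <- curve$I > 0
  # rough Rg from the first positive points to bound the low-angle region
  n_rough <- min(sum(pos), 60L)
  idx_pos <- which(pos)
  rough <- tryCatch({
    ii <- idx_pos[seq_len(n_rough)]
    f <- wls_line(curve$s[ii]^2, log(curve$I[ii]))
    if (f$slope < 0) sqrt(-3 * f$slope) else NA_real_
  }, error = function(e) NA_real_)
  n <- length(curve$s)
  n_low <- if (is.finite(rough)) {
    max(min_window + 2L, sum(curve$s <= 1.5 * srg_limit / rough))
  } else n
  n_low <- min(n_low, n, 400L)
  best <- NULL
  for (i in seq_len(n_low - min_window + 1L)) {
    for (j in seq.int(i + min_window - 1L, n_low)) {
      ii <- i:j
      if (any(curve$I[ii] <= 0)) next
      x <- curve$s[ii]^2
      y <- log(curve$I[ii])
      sig <- if (!is.null(curve$sigma)) curve$sigma[ii] / curve$I[ii] else NULL
      f <- tryCatch(wls_line(x, y, sig), error = function(e) NULL)
      if (is.null(f) || f$slope >= 0) next
      rg <- sqrt(-3 * f$slope)
      if (curve$s[j] * rg > srg_limit) next
      if (f$p_value > p_threshold) next
      qual <- quality_weights[1] * (j - i + 1L) / n_low +
        quality_weights[2] * (1 - (i - 1L) / n_low) +
        quality_weights[3] * max(0, f$r2)
      qual <- qual / sum(quality_weights)
      if (is.null(best) || qual > best$quality) {
        best <- list(
          rg = rg, i0 = exp(f$intercept),
          rg_err = 3 * f$slope_err / (2 * rg),
          i0_err = exp(f$intercept) * f$intercept_err,
          first_point = i, last_point = j,
          quality = qual, srg_max = curve$s[j] * rg, r2 = f$r2)
      }
    }
  }
  if (is.null(best)) {
    stop("no valid Guinier region found (possible aggregation or bad subtraction)",
         call. = FALSE)
  }
  structure(best, class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf("Rg = %.3f +/- %.3f  I(0) = %.4g +/- %.2g  points %d-%d  sRg(max) = %.2f  quality %.2f\n",
              x$rg, x$rg_err, x$i0, x$i0_err, x$first_point, x$last_point,
              x$srg_max, x$quality))
  invisible(x)
}

#' Scale a curve by a constant
#' @param curve a \code{\link{saxs_curve}}.
#' @param k multiplier applied to I and sigma.
#' @return a scaled \code{saxs_curve}.
#' @export
curve_scale <- function(curve, k) {
  stopifnot(inherits(curve, "saxs_curve"), is.finite(k))
  curve$I <- curve$I * k
  if (!is.null(curve$sigma)) curve$sigma <- curve$sigma * abs(k)
  curve
}

#' @noRd
check_grids <- function(a, b, interpolate) {
  same <- length(a$s) == length(b$s) &&
    all(abs(a$s - b$s) <= 1e-6 * pmax(a$s, .Machine$double.eps))
  if (same) return(b)
  if (!interpolate) {
    stop("incompatible s grids; pass interpolate = TRUE to interpolate b onto a",
         call. = FALSE)
  }
  keep <- a$s >= min(b$s) - 1e-12 & a$s <= max(b$s) + 1e-12
  if (!any(keep)) stop("curves do not overlap in s", call. = FALSE)
  I <- interp_curve_values(b$s, b$I, a$s[keep])
  sg <- if (!is.null(b$sigma)) interp_curve_values(b$s, b$sigma, a$s[keep]) else NULL
  list(curve = saxs_curve(a$s[keep], I, sg, label = b$label, unit = b$unit),
       keep = keep)
}

#' Pointwise arithmetic between two curves
#'
#' \code{curve_subtract}/\code{curve_add} propagate sigma in quadrature;
#' \code{curve_multiply} multiplies intensities pointwise.
#'
#' @param a,b \code{\link{saxs_curve}} objects on compatible grids (pointwise
#'   equal s within 1e-6 relative), or set \code{interpolate = TRUE} to
#'   interpolate \code{b} linearly onto \code{a}'s grid (never extrapolating).
#' @param interpolate allow linear interpolation of \code{b}.
#' @return a \code{saxs_curve} on \code{a}'s (possibly trimmed) grid.
#' @export
curve_subtract <- function(a, b, interpolate = FALSE) {
  curve_binop(a, b, interpolate, function(x, y) x - y, quad_sigma = TRUE)
}

#' @rdname curve_subtract
#' @export
curve_add <- function(a, b, interpolate = FALSE) {
  curve_binop(a, b, interpolate, function(x, y) x + y, quad_sigma = TRUE)
}

#' @rdname curve_subtract
#' @export
curve_multiply <- function(a, b, interpolate = FALSE) {
  curve_binop(a, b, interpolate, function(x, y) x * y, quad_sigma = FALSE)
}

#' @noRd
curve_binop <- function(a, b, interpolate, op, quad_sigma) {
  stopifnot(inherits(a, "saxs_curve"), inherits(b, "saxs_curve"))
  bb <- check_grids(a, b, interpolate)
  if (is.list(bb) && !inherits(bb, "saxs_curve")) {
    keep <- bb$keep; bb <- bb$curve
    a <- saxs_curve(a$s[keep], a$I[keep],
                    if (!is.null(a$sigma)) a$sigma[keep], label = a$label,
                    unit = a$unit)
  }
  I <- op(a$I, bb$I)
  sigma <- NULL
  if (!is.null(a$sigma) && !is.null(bb$sigma)) {
    sigma <- if (quad_sigma) sqrt(a$sigma^2 + bb$sigma^2)
    else sqrt((bb$I * a$sigma)^2 + (a$I * bb$sigma)^2)
    sigma[sigma <= 0] <- .Machine$double.eps
  }
  out <- saxs_curve(a$s, I, sigma, label = a$label, unit = a$unit)
  out
}

#' Average several curves
#'
#' Inverse-variance weighted when every curve carries uncertainties,
#' arithmetic otherwise; optional explicit weights override both.
#'
#' @param curves list of \code{\link{saxs_curve}} on compatible grids.
#' @param weights optional per-curve weights.
#' @param interpolate allow interpolation onto the first curve's grid.
#' @return the averaged \code{saxs_curve}.
#' @export
curve_average <- function(curves, weights = NULL, interpolate = FALSE) {
  stopifnot(length(curves) >= 1L)
  ref <- curves[[1L]]
  curves <- lapply(curves, function(cu) {
    r <- check_grids(ref, cu, interpolate)
    if (is.list(r) && !inherits(r, "saxs_curve")) r$curve else r
  })
  Imat <- vapply(curves, function(cu) cu$I, numeric(length(ref$s)))
  have_sig <- all(vapply(curves, function(cu) !is.null(cu$sigma), logical(1)))
  if (!is.null(weights)) {
    w <- matrix(rep(weights, each = length(ref$s)), nrow = length(ref$s))
  } else if (have_sig) {
    w <- vapply(curves, function(cu) 1 / cu$sigma^2, numeric(length(ref$s)))
  } else {
    w <- matrix(1, length(ref$s), length(curves))
  }
  if (is.null(dim(w))) w <- matrix(w, ncol = length(curves))
  I <- rowSums(Imat * w) / rowSums(w)
  sigma <- if (have_sig && is.null(weights)) sqrt(1 / rowSums(w)) else NULL
  saxs_curve(ref$s, I, sigma, label = ref$label, unit = ref$unit)
}

#' Statistical comparison of two curves
#'
#' Finds the optimal scale \code{c} between the curves by weighted least
#' squares, then the reduced chi-square
#' \deqn{\chi^2_{red} = \frac{1}{N-1} \sum \frac{(I_a - c I_b)^2}{\sigma_a^2 + c^2 \sigma_b^2}}
#' and its chi-square p-value. Curves are declared similar when
#' \code{p >= p_similar}.
#'
#' @param a,b \code{\link{saxs_curve}} objects with an overlapping s-range of
#'   at least 10 common points (b is interpolated onto a where needed).
#' @param range optional numeric length 2 restricting the comparison.
#' @param p_similar similarity threshold on the p-value.
#' @return list with \code{chi2_reduced}, \code{p_value},
#'   \code{scale_applied} (the factor applied to b), \code{n} and
#'   \code{similar}.
#' @export
curve_compare <- function(a, b, range = NULL, p_similar = 0.01) {
  stopifnot(inherits(a, "saxs_curve"), inherits(b, "saxs_curve"))
  if (!is.null(range)) {
    a <- curve_window(a, range); b <- curve_window(b, range)
  }
  bb <- check_grids(a, b, interpolate = TRUE)
  if (is.list(bb) && !inherits(bb, "saxs_curve")) {
    keep <- bb$keep
    a <- curve_index(a, which(keep))
    bb <- bb$curve
  }
  n <- length(a$s)
  if (n < 10L) stop("fewer than 10 overlapping points", call. = FALSE)
  sa <- a$sigma %||% rep(1, n)
  sb <- bb$sigma %||% rep(0, n)
  chi2_of <- function(cc) {
    sum((a$I - cc * bb$I)^2 / (sa^2 + cc^2 * sb^2)) / (n - 1L)
  }
  # start from the plain weighted LS scale, then refine the error-in-both
  # objective in 1-D
  c0 <- sum(a$I * bb$I / sa^2) / sum(bb$I^2 / sa^2)
  opt <- stats::optimize(chi2_of, interval = c(0, max(4 * abs(c0), 1e-8)))
  cc <- if (opt$objective <= chi2_of(c0)) opt$minimum else c0
  chi2 <- chi2_of(cc)
  p <- stats::pchisq(chi2 * (n - 1L), df = n - 1L, lower.tail = FALSE)
  list(chi2_reduced = chi2, p_value = p, scale_applied = cc, n = n,
       similar = p >= p_similar)
}

#' @noRd
curve_window <- function(curve, range) {
  keep <- which(curve$s >= range[1] & curve$s <= range[2])
  if (length(keep) == 0L) stop("no points in requested s-range", call. = FALSE)
  curve_index(curve, keep)
}

#' @noRd
curve_index <- function(curve, idx) {
  out <- saxs_curve(curve$s[idx], curve$I[idx],
                    if (!is.null(curve$sigma)) curve$sigma[idx],
                    concentration = curve$concentration,
                    label = curve$label, unit = curve$unit)
  if (!is.null(curve$I_fit)) out$I_fit <- curve$I_fit[idx]
  out
}

#' Merge a low-angle and a high-angle curve
#'
#' The high-angle curve is scaled onto the low-angle one inside the overlap
#' window (using \code{\link{curve_compare}}'s optimal scale); the output
#' takes the low curve below the window, the scaled high curve above it, and
#' an inverse-variance blend inside it. The s grid is the union of both.
#'
#' @param low,high \code{\link{saxs_curve}} objects overlapping in
#'   \code{window}.
#' @param window numeric length 2; defaults to the full overlap.
#' @return the merged \code{saxs_curve}.
#' @export
curve_merge <- function(low, high, window = NULL) {
  stopifnot(inherits(low, "saxs_curve"), inherits(high, "saxs_curve"))
  lo <- max(min(low$s), min(high$s))
  hi <- min(max(low$s), max(high$s))
  if (lo >= hi) stop("curves have disjoint s-ranges", call. = FALSE)
  if (is.null(window)) window <- c(lo, hi)
  window <- c(max(window[1], lo), min(window[2], hi))
  cmp <- curve_compare(low, high, range = window)
  high <- curve_scale(high, cmp$scale_applied)
  s_all <- sort(unique(c(low$s, high$s)))
  pick <- function(cur, s) {
    ok <- s >= min(cur$s) - 1e-12 & s <= max(cur$s) + 1e-12
    I <- rep(NA_real_, length(s)); sg <- rep(NA_real_, length(s))
    I[ok] <- interp_curve_values(cur$s, cur$I, s[ok])
    if (!is.null(cur$sigma)) sg[ok] <- interp_curve_values(cur$s, cur$sigma, s[ok])
    list(I = I, sigma = sg)
  }
  L <- pick(low, s_all); H <- pick(high, s_all)
  I <- numeric(length(s_all)); sg <- numeric(length(s_all))
  below <- s_all < window[1] | (is.na(H$I) & !is.na(L$I))
  above <- s_all > window[2] | (is.na(L$I) & !is.na(H$I))
  blend <- !below & !above
  I[below] <- L$I[below]; sg[below] <- L$sigma[below]
  I[above] <- H$I[above]; sg[above] <- H$sigma[above]
  if (any(blend)) {
    wl <- 1 / L$sigma[blend]^2; wh <- 1 / H$sigma[blend]^2
    wl[!is.finite(wl)] <- 1; wh[!is.finite(wh)] <- 1
    I[blend] <- (L$I[blend] * wl + H$I[blend] * wh) / (wl + wh)
    sg[blend] <- sqrt(1 / (wl + wh))
  }
  have_sig <- !is.null(low$sigma) && !is.null(high$sigma)
  saxs_curve(s_all, I, if (have_sig) sg, label = low$label, unit = low$unit)
}
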