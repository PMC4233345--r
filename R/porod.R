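# Porod analysis: background-constant subtraction enforcing the s^-4 decay,
# the Porod invariant Q, excluded particle volume V_P = 2 pi^2 I(0) / Q and
# the molecular-mass estimate MM = ratio * V_P.

#' Estimate the Porod background constant
#'
#' Fits \eqn{I(s) = A + K / s^4} over the highest-angle fraction of the
#' working range, so that subtracting \code{a_const} enforces the Porod
#' decay of a homogeneous particle. The regression is performed on the
#' Porod plot, \eqn{s^4 I(s) = A s^4 + K}, which averages the residual
#' form-factor oscillations of compact bodies evenly across the window
#' (the two parametrisations agree exactly on data that follow the model).
#' \code{a_const} is clamped so that \eqn{I - A} stays positive over the
#' fitted tail.
#'
#' @param curve a \code{\link{saxs_curve}} (Angstrom^-1 grid).
#' @param rg radius of gyration, used to exclude the Guinier region.
#' @param tail_fraction fraction of the working range used for the tail
#'   fit. The default 0.5 spans at least one full oscillation period of
#'   compact-particle form factors over the usual integration range
#'   (about 8/Rg); much shorter windows make A phase-sensitive.
#' @param s_range optional working range (defaults to the full curve beyond
#'   the Guinier region, s > 1.3 / Rg).
#' @return list with \code{a_const}, \code{tail_k} (Porod amplitude),
#'   \code{clamped} flag and the fitted point indices.
#' @export
estimate_background <- function(curve, rg, tail_fraction = 0.5,
                                s_range = NULL) {
  stopifnot(inherits(curve, "saxs_curve"), rg > 0)
  if (is.null(s_range)) s_range <- c(1.3 / rg, max(curve$s))
  idx <- which(curve$s >= s_range[1] & curve$s <= s_range[2] & curve$s > 0)
  if (length(idx) < 5L) {
    stop("curve does not extend beyond the Guinier region", call. = FALSE)
  }
  n_tail <- max(5L, ceiling(tail_fraction * length(idx)))
  tail_idx <- idx[(length(idx) - n_tail + 1L):length(idx)]
  s4 <- curve$s[tail_idx]^4
  y <- curve$I[tail_idx] * s4
  # unweighted on purpose: the residuals here are dominated by coherent
  # form-factor oscillation, not by counting noise, and error weighting
  # would fixate the fit on the oscillation minima
  f <- wls_line(s4, y)
  if (f$intercept <= 0) {
    stop("no s^-4 regime found in the tail (Porod amplitude K <= 0)",
         call. = FALSE)
  }
  a <- f$slope
  clamped <- FALSE
  if (a >= min(curve$I[tail_idx])) {  # keep I - A > 0 over the fitted tail
    a <- min(curve$I[tail_idx]) * (1 - 1e-6)
    clamped <- TRUE
  }
  list(a_const = a, tail_k = f$intercept, clamped = clamped,
       tail_idx = tail_idx)
}

#' Porod invariant, excluded volume and molecular mass
#'
#' Computes \eqn{Q = \int s^2 (I(s) - A) \, ds} as the sum of (i) the
#' Guinier-model continuation on \eqn{[0, s_{min}]}, (ii) trapezoidal
#' integration of the data on \eqn{[s_{min}, s_{max}]}, and (iii) the
#' analytic Porod tail \eqn{K / s_{max}} for \eqn{(s_{max}, \infty)}.
#' Then \eqn{V_P = 2\pi^2 I(0) / Q} and \eqn{MM = ratio \cdot V_P}
#' with the default protein calibration ratio of 0.625 kDa per nm^3.
#'
#' @param curve a \code{\link{saxs_curve}} in Angstrom^-1 (pass
#'   \code{unit = "nm"} curves through \code{\link{convert_unit}} first).
#' @param guinier a \code{guinier_result} from \code{\link{autorg}}.
#' @param s_max upper integration bound; default \code{smax_rg / Rg},
#'   clipped to the curve end. When \code{second_minimum = TRUE} and a
#'   second minimum of the Porod plot \eqn{s^4 I(s)} is found below that
#'   bound, the minimum is used instead.
#' @param smax_rg the default cutoff multiple of 1/Rg.
#' @param ratio molecular-mass calibration, kDa per nm^3 of V_P.
#' @param tail_fraction passed to \code{\link{estimate_background}}.
#' @param second_minimum use the second minimum of the Porod plot as the
#'   cutoff when detectable.
#' @return a \code{porod_result}: list with \code{a_const}, \code{tail_k},
#'   \code{q_invariant}, \code{v_porod} (Angstrom^3), \code{mm_kda},
#'   \code{s_min}, \code{s_max}.
#' @export
porod_volume <- function(curve, guinier, s_max = NULL, smax_rg = 8,
                         ratio = 0.625, tail_fraction = 0.5,
                         second_minimum = FALSE) {
  stopifnot(inherits(curve, "saxs_curve"), inherits(guinier, "guinier_result"))
  rg <- guinier$rg; i0 <- guinier$i0
  s_min <- curve$s[guinier$first_point]
  if (is.null(s_max)) s_max <- min(smax_rg / rg, max(curve$s))
  if (second_minimum) {
    sm <- porod_second_minimum(curve, rg)
    if (is.finite(sm)) s_max <- min(s_max, sm)
  }
  if (s_min >= s_max) stop("empty integration range", call. = FALSE)
  bg <- estimate_background(curve, rg, tail_fraction = tail_fraction,
                            s_range = c(s_min, s_max))
  idx <- which(curve$s >= s_min & curve$s <= s_max)
  s <- curve$s[idx]
  y <- s^2 * (curve$I[idx] - bg$a_const)
  q_data <- trapz_int(s, y)
  # Guinier continuation on [0, s_min]
  q_head <- stats::integrate(function(t) t^2 * i0 * exp(-t^2 * rg^2 / 3),
                             lower = 0, upper = s_min)$value
  q_tail <- bg$tail_k / s_max
  q <- q_head + q_data + q_tail
  if (q <= 0) {
    stop("Porod invariant non-positive after constant subtraction (over-subtraction)",
         call. = FALSE)
  }
  vp <- 2 * pi^2 * i0 / q
  structure(list(a_const = bg$a_const, tail_k = bg$tail_k,
                 q_invariant = q, q_head = q_head, q_tail = q_tail,
                 v_porod = vp, mm_kda = ratio * vp / 1000,
                 s_min = s_min, s_max = s_max, rg = rg, i0 = i0,
                 clamped = bg$clamped),
            class = "porod_result")
}

# Second minimum of the Porod plot s^4 * I(s), searched beyond the Guinier
# region; returns NA when fewer than two local minima exist.
#' @noRd
porod_second_minimum <- function(curve, rg) {
  idx <- which(curve$s > 1.3 / rg)
  if (length(idx) < 7L) return(NA_real_)
  s <- curve$s[idx]
  y <- s^4 * curve$I[idx]
  # light smoothing to stabilise minima detection on noisy data
  if (length(y) > 11L) y <- stats::filter(y, rep(1 / 5, 5), sides = 2)
  ok <- !is.na(y)
  s <- s[ok]; y <- y[ok]
  dmin <- which(diff(sign(diff(y))) > 0) + 1L
  if (length(dmin) < 2L) return(NA_real_)
  s[dmin[2L]]
}

#' @export
print.porod_result <- function(x, ...) {
  cat(sprintf("Porod analysis: A = %.4g, K = %.4g, Q = %.4g\n",
              x$a_const, x$tail_k, x$q_invariant))
  cat(sprintf("  V_P = %.0f A^3, MM = %.1f kDa  (range %.4f - %.4f A^-1)\n",
              x$v_porod, x$mm_kda, x$s_min, x$s_max))
  invisible(x)
}

#' Convert the s-grid unit of a curve
#'
#' @param curve a \code{\link{saxs_curve}}.
#' @param to target unit, \code{"A"} or \code{"nm"} (inverse lengths).
#' @return the converted curve.
#' @export
convert_unit <- function(curve, to = c("A", "nm")) {
  to <- match.arg(to)
  if (identical(curve$unit, to)) return(curve)
  fac <- if (to == "A") 1 / 10 else 10   # nm^-1 -> A^-1 divides s by 10
  out <- saxs_curve(curve$s * fac, curve$I, curve$sigma,
                    concentration = curve$concentration,
                    label = curve$label, unit = to)
  out$I_fit <- curve$I_fit
  out
}

#' Unattended Guinier + Porod pipeline
#'
#' Chains \code{\link{autorg}} and \code{\link{porod_volume}} (with
#' optional Savitzky-Golay smoothing in between) so that particle volume
#' and molecular mass can be estimated without human intervention, e.g.
#' inside beamline pipelines. Errors from the sub-steps are re-raised with
#' a stage label.
#'
#' @param curve a \code{\link{saxs_curve}}; nm^-1 grids are converted.
#' @param smooth apply a light local-polynomial smoothing before
#'   integration (requires the \pkg{signal} package; off by default).
#' @param ... passed to \code{\link{porod_volume}}.
#' @return a \code{porod_result} with the \code{guinier_result} attached as
#'   \code{$guinier}.
#' @export
autoporod <- function(curve, smooth = FALSE, ...) {
  stopifnot(inherits(curve, "saxs_curve"))
  if (identical(curve$unit, "nm")) curve <- convert_unit(curve, "A")
  g <- tryCatch(autorg(curve),
                error = function(e) stop("autorg stage: ", conditionMessage(e),
                                         call. = FALSE))
  work <- curve
  if (smooth && requireNamespace("signal", quietly = TRUE) &&
      length(curve$s) >= 11L) {
    work$I <- as.numeric(signal::sgolayfilt(curve$I, p = 3, n = 11))
  }
  res <- tryCatch(porod_volume(work, g, ...),
                  error = function(e) stop("porod stage: ", conditionMessage(e),
                                           call. = FALSE))
  res$guinier <- g
  res
}
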