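# Concentration-series processing: consistency checking, scaling,
# pointwise extrapolation to infinite dilution, diagnostics and final merge.
#
# The model is a linear concentration effect,
#   I(s, c) = I(s, 0) + c * B(s),
# where B(s) collects interparticle-interference contributions that are
# proportional to concentration over the measured range.

#' Bundle a concentration series
#'
#' @param curves list of \code{\link{saxs_curve}} objects, each with a
#'   positive \code{concentration}; at least two distinct concentrations.
#' @param concentrations optional numeric vector overriding the per-curve
#'   metadata.
#' @return an object of class \code{dilution_series}.
#' @export
dilution_series <- function(curves, concentrations = NULL) {
  stopifnot(length(curves) >= 2L)
  if (!is.null(concentrations)) {
    stopifnot(length(concentrations) == length(curves))
    for (i in seq_along(curves)) curves[[i]]$concentration <- concentrations[i]
  }
  conc <- vapply(curves, function(cu) cu$concentration %||% NA_real_, numeric(1))
  if (any(is.na(conc)) || any(conc <= 0)) {
    stop("every curve needs a positive concentration", call. = FALSE)
  }
  if (length(unique(conc)) < 2L) {
    stop("at least two distinct concentrations required", call. = FALSE)
  }
  structure(list(curves = curves, concentrations = conc,
                 fit_range = NULL, scales = NULL),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  cat("dilution_series:", length(x$curves), "curves, c =",
      paste(format(x$concentrations, digits = 3), collapse = ", "), "mg/ml\n")
  if (!is.null(x$fit_range)) {
    cat("  fit range: [", format(x$fit_range[1], digits = 4), ",",
        format(x$fit_range[2], digits = 4), "]\n")
  }
  invisible(x)
}

#' Set the fitting range and scales of a series by hand
#'
#' Normally \code{\link{find_fit_range}} determines both; this setter
#' supports workflows where the scales are known exactly (e.g. synthetic
#' data or absolute-scale measurements).
#'
#' @param series a \code{\link{dilution_series}}.
#' @param range numeric length 2, the s-interval where profiles coincide.
#' @param scales per-curve multiplier onto the common scale (default 1).
#' @return the updated series.
#' @export
set_fit_range <- function(series, range, scales = NULL) {
  stopifnot(inherits(series, "dilution_series"), length(range) == 2L)
  series$fit_range <- as.numeric(range)
  series$scales <- scales %||% rep(1, length(series$curves))
  series$reference <- which.max(series$concentrations)
  series
}

#' Find the optimal high-angle fitting range of a concentration series
#'
#' Scans candidate high-angle windows; in each, every curve is scaled onto
#' the most concentrated one and all pairwise reduced chi-squares are
#' computed. The widest window in which all pairs are statistically similar
#' is returned, together with the scales, confirming that the sample
#' identity is consistent across the series (the profiles coincide at
#' higher angles after scaling). Curves that never match are flagged.
#'
#' @param series a \code{\link{dilution_series}}.
#' @param p_threshold pairwise-similarity threshold on the p-value.
#' @param n_candidates number of candidate window start points scanned.
#' @return the series with \code{fit_range} (numeric length 2),
#'   \code{scales} (multiplier per curve onto the reference) and
#'   \code{outliers} (indices of curves failing the identity check) filled
#'   in.
#' @export
find_fit_range <- function(series, p_threshold = 0.01, n_candidates = 12L) {
  stopifnot(inherits(series, "dilution_series"))
  cs <- series$curves
  ref <- which.max(series$concentrations)
  s_lo_all <- max(vapply(cs, function(cu) min(cu$s), numeric(1)))
  s_hi <- min(vapply(cs, function(cu) max(cu$s), numeric(1)))
  if (s_lo_all >= s_hi) stop("curves do not share an s-range", call. = FALSE)
  starts <- seq(s_lo_all, s_lo_all + 0.9 * (s_hi - s_lo_all),
                length.out = n_candidates)
  check_window <- function(w) {
    scales <- rep(1, length(cs))
    ok <- TRUE
    pmin_seen <- 1
    for (i in seq_along(cs)) {
      if (i == ref) next
      cmp <- tryCatch(curve_compare(cs[[ref]], cs[[i]], range = w,
                                    p_similar = p_threshold),
                      error = function(e) NULL)
      if (is.null(cmp)) return(NULL)
      scales[i] <- cmp$scale_applied
      if (!cmp$similar) ok <- FALSE
      pmin_seen <- min(pmin_seen, cmp$p_value)
    }
    list(ok = ok, scales = scales, pmin = pmin_seen)
  }
  chosen <- NULL
  for (st in starts) {
    w <- c(st, s_hi)
    res <- check_window(w)
    if (!is.null(res) && res$ok) { chosen <- c(res, list(window = w)); break }
  }
  if (is.null(chosen)) {
    # identify the outlier(s): curves failing pairwise similarity against the
    # reference in the widest window that any subset supports
    w <- c(starts[length(starts)], s_hi)
    bad <- integer(0)
    for (i in seq_along(cs)) {
      if (i == ref) next
      cmp <- tryCatch(curve_compare(cs[[ref]], cs[[i]], range = w,
                                    p_similar = p_threshold),
                      error = function(e) NULL)
      if (is.null(cmp) || !cmp$similar) bad <- c(bad, i)
    }
    stop("no fitting range where all curves match after scaling; ",
         "inconsistent curve(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  series$fit_range <- chosen$window
  series$scales <- chosen$scales
  series$reference <- ref
  series$outliers <- integer(0)
  series
}

#' Pointwise extrapolation of a concentration series to zero concentration
#'
#' At each common grid point the scaled intensities are regressed linearly
#' against concentration by weighted least squares: the intercept is the
#' infinite-dilution intensity \eqn{I(s, 0)} with its standard error, the
#' slope is the concentration-effect term \eqn{B(s)}.
#'
#' Three diagnostics are computed: (a) \code{rg_consistent} compares the
#' Guinier Rg of the extrapolated curve with a straight-line extrapolation
#' of the per-curve Rg values to c = 0; (b) the pointwise intercept error
#' must stay within \code{kappa} times the smallest input error; (c)
#' \code{info_gain} flags points where the extrapolated value differs from
#' every input value by more than \code{info_scale} times the intercept
#' error.
#'
#' @param series a \code{\link{dilution_series}} with \code{fit_range} and
#'   \code{scales} (from \code{\link{find_fit_range}}; computed on the fly
#'   otherwise).
#' @param rg_tolerance relative tolerance of the Rg consistency check.
#' @param kappa error-inflation bound for the pointwise error check.
#' @param info_scale multiple of the propagated intercept sigma above which
#'   an extrapolated point counts as new information.
#' @param rg_squared regress per-curve Rg^2 (Guinier-additive, default) or
#'   plain Rg against c for the linear Rg prediction.
#' @return an \code{extrapolation_report}: list with \code{i_zero_curve},
#'   \code{b_curve}, \code{rg_extrapolated}, \code{rg_linear_pred},
#'   \code{rg_consistent}, \code{error_ok}, \code{info_gain} and
#'   \code{merge_point}.
#' @export
extrapolate_zero <- function(series, rg_tolerance = 0.05, kappa = 5,
                             info_scale = 3, rg_squared = TRUE) {
  stopifnot(inherits(series, "dilution_series"))
  if (is.null(series$fit_range)) series <- find_fit_range(series)
  cs <- series$curves
  conc <- series$concentrations
  if (length(unique(conc)) < 2L) stop("need >= 2 distinct concentrations", call. = FALSE)
  ref <- series$reference %||% which.max(conc)
  scaled <- lapply(seq_along(cs), function(i) curve_scale(cs[[i]], series$scales[i]))
  # common grid: reference grid restricted to the intersection of ranges
  s_lo <- max(vapply(cs, function(cu) min(cu$s), numeric(1)))
  s_hi <- min(vapply(cs, function(cu) max(cu$s), numeric(1)))
  s_common <- scaled[[ref]]$s[scaled[[ref]]$s >= s_lo & scaled[[ref]]$s <= s_hi]
  Imat <- vapply(scaled, function(cu) interp_curve_values(cu$s, cu$I, s_common),
                 numeric(length(s_common)))
  have_sig <- all(vapply(scaled, function(cu) !is.null(cu$sigma), logical(1)))
  Smat <- if (have_sig) {
    vapply(scaled, function(cu) interp_curve_values(cu$s, cu$sigma, s_common),
           numeric(length(s_common)))
  } else matrix(1, length(s_common), length(cs))
  i0 <- b <- i0_err <- numeric(length(s_common))
  for (p in seq_along(s_common)) {
    f <- wls_line(conc, Imat[p, ], Smat[p, ])
    i0[p] <- f$intercept; b[p] <- f$slope; i0_err[p] <- f$intercept_err
  }
  i_zero <- saxs_curve(s_common, i0, if (have_sig) pmax(i0_err, 1e-300),
                       label = "extrapolated to c = 0",
                       unit = cs[[1]]$unit)
  b_curve <- saxs_curve(s_common, b, label = "concentration effect B(s)",
                        unit = cs[[1]]$unit)
  # Rg diagnostics
  rg_ext <- tryCatch(autorg(i_zero)$rg, error = function(e) NA_real_)
  rg_in <- vapply(cs, function(cu) {
    tryCatch(autorg(cu)$rg, error = function(e) NA_real_)
  }, numeric(1))
  ok <- is.finite(rg_in)
  rg_lin <- if (sum(ok) >= 2L) {
    y <- if (rg_squared) rg_in[ok]^2 else rg_in[ok]
    f <- wls_line(conc[ok], y)
    if (rg_squared) sqrt(max(f$intercept, 0)) else f$intercept
  } else NA_real_
  rg_consistent <- is.finite(rg_ext) && is.finite(rg_lin) &&
    abs(rg_ext - rg_lin) <= rg_tolerance * rg_lin
  error_ok <- !have_sig || all(i0_err <= kappa * apply(Smat, 1L, min))
  diff_min <- apply(abs(Imat - i0), 1L, min)
  info_gain <- diff_min > info_scale * i0_err
  structure(list(i_zero_curve = i_zero, b_curve = b_curve,
                 rg_extrapolated = rg_ext, rg_linear_pred = rg_lin,
                 rg_consistent = rg_consistent, error_ok = error_ok,
                 info_gain = info_gain, s_common = s_common,
                 scaled_curves = scaled, merge_point = NULL),
            class = "extrapolation_report")
}

#' @export
print.extrapolation_report <- function(x, ...) {
  cat(sprintf("extrapolation to c = 0: Rg %.2f (linear prediction %.2f) -> %s\n",
              x$rg_extrapolated, x$rg_linear_pred,
              if (isTRUE(x$rg_consistent)) "consistent" else "INCONSISTENT"))
  cat(sprintf("  info gain at %d / %d points; pointwise errors %s\n",
              sum(x$info_gain), length(x$info_gain),
              if (isTRUE(x$error_ok)) "ok" else "inflated"))
  invisible(x)
}

#' Merge the extrapolated curve with the averaged high-angle data
#'
#' Below the merge point the output is the infinite-dilution extrapolation;
#' above it, the inverse-variance average of the scaled input curves. The
#' merge point is the s value inside the fitting range minimising the
#' normalised discontinuity |I_left - I_right| / sigma.
#'
#' @param report an \code{extrapolation_report}.
#' @param series the \code{\link{dilution_series}} it came from.
#' @return the merged \code{\link{saxs_curve}}; the chosen merge point is
#'   attached as attribute \code{"merge_point"}.
#' @export
merge_extrapolated <- function(report, series) {
  stopifnot(inherits(report, "extrapolation_report"),
            inherits(series, "dilution_series"))
  if (is.null(series$fit_range)) series <- find_fit_range(series)
  s <- report$s_common
  avg <- curve_average(report$scaled_curves, interpolate = TRUE)
  avg_I <- interp_curve_values(avg$s, avg$I, s)
  ext <- report$i_zero_curve
  in_range <- which(s >= series$fit_range[1] & s <= series$fit_range[2])
  if (length(in_range) == 0L) in_range <- seq_along(s)
  sig <- ext$sigma %||% rep(stats::sd(ext$I) + 1e-12, length(s))
  jump <- abs(ext$I[in_range] - avg_I[in_range]) / sig[in_range]
  mp_idx <- in_range[which.min(jump)]
  merge_point <- s[mp_idx]
  I <- ifelse(s <= merge_point, ext$I, avg_I)
  sg <- NULL
  if (!is.null(ext$sigma) && !is.null(avg$sigma)) {
    avg_sg <- interp_curve_values(avg$s, avg$sigma, s)
    sg <- ifelse(s <= merge_point, ext$sigma, avg_sg)
  }
  out <- saxs_curve(s, I, sg, label = "merged infinite-dilution curve",
                    unit = ext$unit)
  attr(out, "merge_point") <- merge_point
  out
}

#' One-call dilution-series processing
#'
#' Runs \code{\link{find_fit_range}}, \code{\link{extrapolate_zero}} and
#' \code{\link{merge_extrapolated}} in sequence.
#'
#' @param series a \code{\link{dilution_series}}.
#' @param ... passed to \code{\link{extrapolate_zero}}.
#' @return list with \code{series}, \code{report} and \code{merged}.
#' @export
automerge <- function(series, ...) {
  series <- find_fit_range(series)
  report <- extrapolate_zero(series, ...)
  merged <- merge_extrapolated(report, series)
  list(series = series, report = report, merged = merged)
}
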