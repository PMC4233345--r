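#' Construct a 1-D scattering curve
#'
#' The central container for an isotropic small-angle scattering profile:
#' a momentum-transfer grid \code{s} (convention \eqn{s = 4\pi \sin\theta /
#' \lambda}), intensities \code{I} in arbitrary units, and optional 1-sigma
#' uncertainties.
#'
#' @param s numeric vector, strictly increasing, all non-negative.
#' @param I numeric vector of intensities, same length as \code{s}. Negative
#'   values are allowed (buffer-subtracted data may dip below zero).
#' @param sigma optional numeric vector of positive 1-sigma uncertainties.
#' @param concentration optional solute concentration (mg/ml).
#' @param label free-text label carried through operations.
#' @param unit unit of \code{s}: \code{"A"} (inverse Angstrom, default) or
#'   \code{"nm"} (inverse nanometre).
#' @return an object of class \code{saxs_curve}.
#' @export
#' @examples
#' cur <- saxs_curve(s = c(0.01, 0.02, 0.03), I = c(100, 90, 80),
#'                   sigma = c(1, 1, 1))
#' cur
saxs_curve <- function(s, I, sigma = NULL, concentration = NULL,
                       label = "", unit = "A") {
  s <- as.numeric(s); I <- as.numeric(I)
  if (length(s) == 0L) stop("empty curve", call. = FALSE)
  if (length(s) != length(I)) stop("s and I must have equal length", call. = FALSE)
  if (any(!is.finite(s)) || any(s < 0)) stop("s must be finite and >= 0", call. = FALSE)
  if (any(diff(s) <= 0)) stop("s must be strictly increasing", call. = FALSE)
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(s)) stop("sigma length mismatch", call. = FALSE)
    if (any(!is.finite(sigma)) || any(sigma <= 0)) {
      stop("sigma must be finite and > 0", call. = FALSE)
    }
  }
  structure(list(s = s, I = I, sigma = sigma,
                 concentration = concentration, label = label, unit = unit),
            class = "saxs_curve")
}

#' @export
print.saxs_curve <- function(x, ...) {
  cat("saxs_curve:", length(x$s), "points, s in [",
      format(min(x$s), digits = 4), ",", format(max(x$s), digits = 4),
      paste0("] ", x$unit, "^-1"),
      if (!is.null(x$sigma)) "with errors" else "no errors", "\n")
  if (nzchar(x$label %||% "")) cat("  label:", x$label, "\n")
  if (!is.null(x$concentration)) cat("  concentration:", x$concentration, "mg/ml\n")
  invisible(x)
}

#' @export
length.saxs_curve <- function(x) length(x$s)

#' Construct a bead model
#'
#' An ordered 3-D point set with per-point scattering weight, used both for
#' dummy-atom/dummy-residue models and for full-atom coordinates collapsed to
#' points.
#'
#' @param coords numeric matrix, n x 3, in Angstrom.
#' @param weight per-point scattering length (recycled), all >= 0.
#' @param radius bead radius in Angstrom (single positive value).
#' @param chain_id,residue_index per-point labels (recycled).
#' @param refinable logical per-point flag (recycled), e.g. surface beads of a
#'   density-derived model.
#' @param label free text.
#' @return an object of class \code{bead_model}.
#' @export
bead_model <- function(coords, weight = 1, radius = 1.9, chain_id = "A",
                       residue_index = NULL, refinable = TRUE, label = "") {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3L) stop("coords must be n x 3", call. = FALSE)
  if (nrow(coords) == 0L) stop("empty model", call. = FALSE)
  if (any(!is.finite(coords))) stop("coordinates must be finite", call. = FALSE)
  n <- nrow(coords)
  weight <- rep_len(as.numeric(weight), n)
  if (any(weight < 0)) stop("weights must be >= 0", call. = FALSE)
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (is.null(residue_index)) residue_index <- seq_len(n)
  structure(list(coords = unname(coords), weight = weight, radius = radius,
                 chain_id = rep_len(chain_id, n),
                 residue_index = rep_len(as.integer(residue_index), n),
                 refinable = rep_len(as.logical(refinable), n),
                 label = label),
            class = "bead_model")
}

#' @export
print.bead_model <- function(x, ...) {
  cat("bead_model:", nrow(x$coords), "points,",
      length(unique(x$chain_id)), "chain(s), radius",
      format(x$radius, digits = 3), "A\n")
  invisible(x)
}

#' Number of points in a bead model
#' @param x a \code{bead_model}.
#' @return integer point count.
#' @export
n_beads <- function(x) nrow(x$coords)

#' Radius of gyration of a bead model
#'
#' Weighted second moment about the centre of scattering mass,
#' \eqn{R_g^2 = \sum w_i |r_i - \bar r|^2 / \sum w_i}.
#'
#' @param model a \code{bead_model}.
#' @return Rg in Angstrom.
#' @export
model_rg <- function(model) {
  w <- model$weight / sum(model$weight)
  ctr <- colSums(model$coords * w)
  d2 <- rowSums(sweep(model$coords, 2, ctr)^2)
  sqrt(sum(w * d2))
}

#' Construct a density grid
#'
#' A 3-D scalar field on a regular grid, as read from an MRC/CCP4 map.
#'
#' @param values 3-D numeric array.
#' @param voxel_size edge length per axis in Angstrom (length 1 or 3).
#' @param origin position of the centre of voxel (1,1,1), in Angstrom.
#' @return an object of class \code{density_grid}.
#' @export
density_grid <- function(values, voxel_size, origin = c(0, 0, 0)) {
  if (length(dim(values)) != 3L) stop("values must be a 3-D array", call. = FALSE)
  voxel_size <- rep_len(as.numeric(voxel_size), 3L)
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("voxel_size must be > 0", call. = FALSE)
  }
  structure(list(values = values, voxel_size = voxel_size,
                 origin = rep_len(as.numeric(origin), 3L)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("density_grid:", paste(dim(x$values), collapse = " x "),
      "voxels,", paste(format(x$voxel_size, digits = 4), collapse = "/"),
      "A voxel size\n")
  invisible(x)
}
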