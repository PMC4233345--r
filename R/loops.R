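# Self-avoiding C-alpha random-loop generation, a library binned by length
# and end-to-end distance, and anchored linker queries.
#
# Geometry rules for a valid trace:
#   - consecutive C-alpha distance exactly 3.8 A
#   - any non-neighbouring pair separated by more than 4 A
#   - pseudo-bond angle theta within the allowed range and the
#     (theta, gamma) pseudo-angle pair outside a forbidden zone of the
#     quasi-Ramachandran plot

#' Default quasi-Ramachandran mask
#'
#' The pseudo-bond angle (three consecutive C-alphas) must lie in
#' \code{theta_range}; additionally, (theta, gamma) pairs inside the
#' rectangular \code{forbidden} zone (a crowded near-cis strip of the
#' pseudo-dihedral) are rejected. The exact empirical region is not fixed
#' by convention, so the mask is a plain list users can tighten.
#'
#' @param theta_range allowed pseudo-bond angle interval, degrees.
#' @param forbidden list with \code{theta} and \code{gamma} intervals
#'   (degrees) delimiting the excluded rectangle.
#' @return a mask list understood by \code{\link{grow_loop}}.
#' @export
quasi_ramachandran_mask <- function(theta_range = c(75, 150),
                                    forbidden = list(theta = c(110, 150),
                                                     gamma = c(-40, 40))) {
  list(theta_range = theta_range, forbidden = forbidden)
}

#' @noRd
ca_bond <- 3.8
#' @noRd
ca_clash <- 4.0

# pseudo-bond angle at b for points a-b-c, degrees
#' @noRd
pseudo_angle <- function(a, b, cc) {
  u <- a - b; v <- cc - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# pseudo-dihedral for points a-b-c-d, degrees in (-180, 180]
#' @noRd
pseudo_dihedral <- function(a, b, cc, d) {
  b1 <- b - a; b2 <- cc - b; b3 <- d - cc
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

#' @noRd
mask_ok <- function(theta, gamma, mask) {
  if (theta < mask$theta_range[1] || theta > mask$theta_range[2]) return(FALSE)
  if (!is.null(gamma) && !is.null(mask$forbidden)) {
    fz <- mask$forbidden
    if (theta >= fz$theta[1] && theta <= fz$theta[2] &&
        gamma >= fz$gamma[1] && gamma <= fz$gamma[2]) return(FALSE)
  }
  TRUE
}

#' Grow one self-avoiding C-alpha trace
#'
#' Sequential growth: each new point is placed 3.8 Angstrom from its
#' predecessor in a direction drawn uniformly on the sphere, accepted only
#' if no non-neighbouring pair comes closer than 4 Angstrom and the
#' pseudo-angle pair passes the quasi-Ramachandran mask. Each step gets a
#' bounded number of retries, with single-step backtracking before the
#' whole trace is restarted.
#'
#' @param n_residues trace length, 2 to 100.
#' @param mask a \code{\link{quasi_ramachandran_mask}}.
#' @param max_retries direction draws per step before backtracking.
#' @param max_restarts whole-trace restarts before giving up.
#' @return a \code{ca_trace}: list with \code{coords} (n x 3 matrix) and
#'   \code{n_residues}.
#' @export
grow_loop <- function(n_residues, mask = quasi_ramachandran_mask(),
                      max_retries = 100L, max_restarts = 50L) {
  stopifnot(n_residues >= 2L, n_residues <= 100L)
  for (restart in seq_len(max_restarts)) {
    coords <- matrix(0, n_residues, 3L)
    coords[2L, ] <- c(ca_bond, 0, 0)
    ok_all <- TRUE
    i <- 3L
    budget <- 200L * n_residues   # bounds backtracking work per restart
    while (i <= n_residues) {
      budget <- budget - 1L
      if (budget <= 0L) { ok_all <- FALSE; break }
      placed <- FALSE
      for (try in seq_len(max_retries)) {
        dir <- random_unit_vectors(1L)[1L, ]
        p <- coords[i - 1L, ] + ca_bond * dir
        theta <- pseudo_angle(coords[i - 2L, ], coords[i - 1L, ], p)
        gamma <- if (i >= 4L) {
          pseudo_dihedral(coords[i - 3L, ], coords[i - 2L, ],
                          coords[i - 1L, ], p)
        } else NULL
        if (!mask_ok(theta, gamma, mask)) next
        if (i > 2L) {
          prev <- coords[seq_len(i - 2L), , drop = FALSE]
          d2 <- rowSums(sweep(prev, 2L, p)^2)
          if (min(d2) <= ca_clash^2) next
        }
        coords[i, ] <- p
        placed <- TRUE
        break
      }
      if (!placed) {
        if (i > 3L) { i <- i - 1L; next }  # single-step backtrack
        ok_all <- FALSE
        break
      }
      i <- i + 1L
    }
    if (ok_all && i > n_residues) {
      return(structure(list(coords = coords, n_residues = n_residues),
                       class = "ca_trace"))
    }
  }
  stop("loop growth failed after ", max_restarts, " restarts", call. = FALSE)
}

#' End-to-end distance of a trace
#' @param trace a \code{ca_trace}.
#' @return distance in Angstrom.
#' @export
end_to_end <- function(trace) {
  sqrt(sum((trace$coords[trace$n_residues, ] - trace$coords[1L, ])^2))
}

#' Validate C-alpha trace geometry
#'
#' @param trace a \code{ca_trace}.
#' @param tol bond-length tolerance.
#' @return TRUE invisibly; errors on violation.
#' @export
validate_trace <- function(trace, tol = 1e-6) {
  x <- trace$coords
  n <- nrow(x)
  bonds <- sqrt(rowSums((x[-1L, , drop = FALSE] - x[-n, , drop = FALSE])^2))
  if (any(abs(bonds - ca_bond) > tol)) {
    stop("consecutive C-alpha distance deviates from 3.8 A", call. = FALSE)
  }
  if (n > 2L) {
    d <- as.matrix(stats::dist(x))
    nb <- abs(row(d) - col(d)) > 1L
    if (any(d[nb] <= ca_clash)) {
      stop("non-neighbouring C-alpha pair within 4 A", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' @export
print.ca_trace <- function(x, ...) {
  cat(sprintf("ca_trace: %d residues, end-to-end %.2f A\n",
              x$n_residues, end_to_end(x)))
  invisible(x)
}

#' @noRd
bin_center_of <- function(d, bin_width = 2) {
  2 * floor(d / bin_width) * bin_width / 2 + bin_width / 2
}

#' Build a binned random-loop library
#'
#' For each length a pool of random traces is generated, binned by
#' end-to-end distance (default discretisation 2 Angstrom, bin centres at
#' odd multiples of 1 Angstrom), and \code{per_bin} mutually distinct
#' traces (pairwise r.m.s.d. after superposition above
#' \code{distinct_rmsd}) are selected per bin. Bins that never collect
#' \code{per_bin} distinct traces within the generation budget are
#' reported under-filled and excluded from the served library.
#'
#' @param lengths integer vector of residue counts, within [5, 100].
#' @param per_bin traces selected per (length, distance) bin.
#' @param bin_width distance discretisation, Angstrom.
#' @param pool_per_length generation budget: traces grown per length.
#' @param distinct_rmsd distinctness threshold, Angstrom.
#' @param seed RNG seed; generation is bit-reproducible per seed.
#' @param mask passed to \code{\link{grow_loop}}.
#' @return a \code{loop_library}: nested list \code{bins[[length]][[bin]]}
#'   of \code{ca_trace} lists, plus an \code{underfilled} report.
#' @export
build_library <- function(lengths = 5:100, per_bin = 20L, bin_width = 2,
                          pool_per_length = 500L, distinct_rmsd = 0.5,
                          seed = 1, mask = quasi_ramachandran_mask()) {
  stopifnot(all(lengths >= 5L), all(lengths <= 100L))
  set.seed(seed)
  bins <- list()
  underfilled <- list()
  for (L in lengths) {
    cand <- list()  # bin centre label -> list of traces
    for (k in seq_len(pool_per_length)) {
      tr <- tryCatch(grow_loop(L, mask = mask), error = function(e) NULL)
      if (is.null(tr)) next
      ctr <- as.character(bin_center_of(end_to_end(tr), bin_width))
      cand[[ctr]] <- c(cand[[ctr]], list(tr))
    }
    kept <- list()
    for (ctr in names(cand)) {
      sel <- list()
      for (tr in cand[[ctr]]) {
        distinct <- all(vapply(sel, function(old) {
          kabsch_rmsd(old$coords, tr$coords) > distinct_rmsd
        }, logical(1)))
        if (distinct) sel <- c(sel, list(tr))
        if (length(sel) == per_bin) break
      }
      if (length(sel) == per_bin) {
        kept[[ctr]] <- sel
      } else {
        underfilled[[as.character(L)]] <-
          c(underfilled[[as.character(L)]],
            stats::setNames(length(sel), ctr))
      }
    }
    bins[[as.character(L)]] <- kept
  }
  structure(list(bins = bins, per_bin = per_bin, bin_width = bin_width,
                 underfilled = underfilled, seed = seed),
            class = "loop_library")
}

#' @export
print.loop_library <- function(x, ...) {
  nb <- sum(vapply(x$bins, length, integer(1)))
  cat("loop_library:", length(x$bins), "length(s),", nb,
      "filled bins x", x$per_bin, "traces, bin width", x$bin_width, "A\n")
  invisible(x)
}

#' Query a linker between two anchors
#'
#' Locates the distance bin matching |anchor_a - anchor_b| for the given
#' length, picks one stored trace at random and rigid-transforms it so its
#' first point coincides with \code{anchor_a} and its end-to-end vector
#' points at \code{anchor_b}. The internal geometry is untouched; the
#' residual endpoint mismatch (at most half a bin width) is reported.
#' When no stored bin matches, \code{NULL} is returned — the rejection
#' signal a rigid-body assembler uses to veto a domain move.
#'
#' @param library a \code{loop_library}.
#' @param n_residues linker length; must be present in the library.
#' @param anchor_a,anchor_b numeric length-3 anchor coordinates.
#' @return a \code{ca_trace} with attribute \code{"endpoint_mismatch"}, or
#'   \code{NULL} when no bin matches the anchor distance.
#' @export
query_linker <- function(library, n_residues, anchor_a, anchor_b) {
  stopifnot(inherits(library, "loop_library"))
  lb <- library$bins[[as.character(n_residues)]]
  if (is.null(lb)) stop("length ", n_residues, " absent from library", call. = FALSE)
  dd <- sqrt(sum((anchor_b - anchor_a)^2))
  ctr <- bin_center_of(dd, library$bin_width)
  traces <- lb[[as.character(ctr)]]
  if (is.null(traces)) return(NULL)
  tr <- traces[[sample.int(length(traces), 1L)]]
  x <- sweep(tr$coords, 2L, tr$coords[1L, ])
  v <- x[nrow(x), ]
  target <- anchor_b - anchor_a
  rot <- rotation_between(v, target)
  x <- x %*% t(rot)
  x <- sweep(x, 2L, anchor_a, `+`)
  out <- structure(list(coords = x, n_residues = tr$n_residues),
                   class = "ca_trace")
  attr(out, "endpoint_mismatch") <- abs(sqrt(sum(v^2)) - dd)
  out
}

# minimal rotation taking direction a to direction b (Rodrigues)
#' @noRd
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  axis <- c(a[2] * b[3] - a[3] * b[2],
            a[3] * b[1] - a[1] * b[3],
            a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(axis^2))
  cc <- sum(a * b)
  if (s < 1e-12) {
    if (cc > 0) return(diag(3))
    # antiparallel: rotate pi about any perpendicular axis
    perp <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    axis <- perp - sum(perp * a) * a
    return(rotation_about_axis(axis, pi))
  }
  rotation_about_axis(axis, atan2(s, cc))
}
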