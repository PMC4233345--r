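# Form-factor assembly and non-negative decomposition of mixture data into
# component volume fractions. For polydisperse systems without
# interparticle interactions the measured profile is the fraction-weighted
# sum of component intensities, I(s) = sum_k v_k I_k(s); the weights are
# found by non-negative linear least squares.

#' Assemble a form-factor set from heterogeneous sources
#'
#' Sources may be experimental or regularised curves
#' (\code{\link{saxs_curve}}), coordinate models (\code{\link{bead_model}},
#' routed through \code{\link{debye_intensity}}), or lists of models (e.g.
#' an NMR ensemble read with \code{read_model(multi = TRUE)}, expanded to
#' one component per model). All components are interpolated linearly onto
#' a common grid.
#'
#' @param sources list of curves, models, or lists of models.
#' @param s_grid optional common grid; defaults to the grid of the first
#'   curve source restricted to the intersection of all ranges, or to 101
#'   points across the intersection when every source is a model.
#' @param labels optional component labels.
#' @param ... passed to \code{\link{debye_intensity}} for model sources.
#' @return a \code{form_factor_set}: list with \code{s}, \code{components}
#'   (matrix, one column per component) and \code{labels}.
#' @export
build_formfactors <- function(sources, s_grid = NULL, labels = NULL, ...) {
  stopifnot(length(sources) >= 1L)
  flat <- list()
  for (src in sources) {
    if (inherits(src, "bead_model") || inherits(src, "saxs_curve")) {
      flat[[length(flat) + 1L]] <- src
    } else if (is.list(src)) {
      for (m in src) flat[[length(flat) + 1L]] <- m
    } else stop("unsupported source type", call. = FALSE)
  }
  is_curve <- vapply(flat, inherits, logical(1), what = "saxs_curve")
  if (is.null(s_grid)) {
    if (any(is_curve)) {
      lo <- max(vapply(flat[is_curve], function(cu) min(cu$s), numeric(1)))
      hi <- min(vapply(flat[is_curve], function(cu) max(cu$s), numeric(1)))
      if (lo >= hi) stop("curve sources have disjoint s-ranges", call. = FALSE)
      ref <- flat[is_curve][[1L]]
      s_grid <- ref$s[ref$s >= lo & ref$s <= hi]
    } else {
      s_grid <- seq(0, 0.5, length.out = 101L)
    }
  }
  comps <- vapply(flat, function(src) {
    if (inherits(src, "saxs_curve")) {
      interp_curve_values(src$s, src$I, s_grid)
    } else {
      debye_intensity(src, s_grid, ...)$I
    }
  }, numeric(length(s_grid)))
  comps <- matrix(comps, nrow = length(s_grid))
  if (is.null(labels)) {
    labels <- vapply(seq_along(flat), function(i) {
      lb <- flat[[i]]$label %||% ""
      if (nzchar(lb)) lb else paste0("component_", i)
    }, character(1))
  }
  structure(list(s = s_grid, components = comps, labels = labels),
            class = "form_factor_set")
}

#' @export
print.form_factor_set <- function(x, ...) {
  cat("form_factor_set:", ncol(x$components), "components on",
      length(x$s), "grid points\n")
  invisible(x)
}

#' Write / read a multi-column form-factor file
#'
#' Column 1 is s; columns 2..K+1 are component intensities. Labels travel
#' in '#' comment lines.
#'
#' @param ff a \code{form_factor_set}.
#' @param path file path.
#' @return \code{write_formfactors}: invisibly, \code{path};
#'   \code{read_formfactors}: a \code{form_factor_set}.
#' @export
write_formfactors <- function(ff, path) {
  stopifnot(inherits(ff, "form_factor_set"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", ff$labels), con)
  mat <- cbind(ff$s, ff$components)
  writeLines(apply(mat, 1L, function(r) paste(sprintf("%.8e", r), collapse = " ")),
             con)
  invisible(path)
}

#' @rdname write_formfactors
#' @export
read_formfactors <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lab <- sub("^#\\s*", "", lines[grepl("^#", lines)])
  dat <- utils::read.table(text = lines[!grepl("^#", lines)])
  m <- unname(as.matrix(dat))
  labels <- if (length(lab) == ncol(m) - 1L) lab else paste0("component_", seq_len(ncol(m) - 1L))
  structure(list(s = m[, 1L], components = m[, -1L, drop = FALSE],
                 labels = labels),
            class = "form_factor_set")
}

# Lawson-Hanson NNLS with a fallback for rank-deficient designs (e.g.
# duplicated components): a tiny Tikhonov ridge makes the active-set
# normal equations full rank and picks the minimum-norm solution, which
# splits weight evenly across exact duplicates.
#' @noRd
nnls_solve <- function(A, y) {
  res <- tryCatch(pracma::lsqnonneg(A, y)$x, error = function(e) NULL)
  if (!is.null(res)) return(res)
  k <- ncol(A)
  lam <- 1e-7 * max(colSums(A^2))
  A_aug <- rbind(A, diag(sqrt(lam), k))
  pracma::lsqnonneg(A_aug, c(y, numeric(k)))$x
}

#' Volume fractions of mixture components by non-negative least squares
#'
#' Solves \eqn{\min_{w_k \ge 0} \sum_j [(I_{exp}(s_j) - \sum_k w_k
#' I_k(s_j)) / \sigma_j]^2} with the Lawson-Hanson NNLS algorithm and
#' reports normalised volume fractions \eqn{v_k = w_k / \sum w} plus the
#' overall scale \eqn{\sum w}. Components with known fractions can be
#' fixed; the remaining weights are then fitted with the fixed part folded
#' into their design columns.
#'
#' @param ff a \code{form_factor_set} (interpolated onto the experimental
#'   grid as needed).
#' @param exp experimental \code{\link{saxs_curve}}.
#' @param fixed optional named or indexed numeric vector of fractions to
#'   fix, e.g. \code{c("2" = 0.3)} or \code{c(dimer = 0.3)}; values must
#'   sum to less than 1 unless all components are fixed.
#' @return a \code{mixture_fit}: list with \code{fractions} (sum to 1),
#'   \code{overall_scale}, \code{chi2_reduced}, \code{fixed_mask}.
#' @export
fit_fractions <- function(ff, exp, fixed = NULL) {
  stopifnot(inherits(ff, "form_factor_set"), inherits(exp, "saxs_curve"))
  k <- ncol(ff$components)
  keep <- exp$s >= min(ff$s) - 1e-12 & exp$s <= max(ff$s) + 1e-12
  if (sum(keep) < 2L) stop("no overlap between data and form factors", call. = FALSE)
  if (k > sum(keep)) stop("more components than data points", call. = FALSE)
  s <- exp$s[keep]
  A <- apply(ff$components, 2L, function(col) interp_curve_values(ff$s, col, s))
  y <- exp$I[keep]
  sg <- if (!is.null(exp$sigma)) exp$sigma[keep] else rep(1, length(y))
  Aw <- A / sg
  yw <- y / sg
  fixed_mask <- rep(FALSE, k)
  fractions <- numeric(k)
  if (is.null(fixed) || length(fixed) == 0L) {
    w <- nnls_solve(Aw, yw)
    total <- sum(w)
    if (total <= 0) {
      warning("degenerate fit: all component weights zero", call. = FALSE)
      fractions <- rep(0, k)
      scale_tot <- 0
    } else {
      fractions <- w / total
      scale_tot <- total
    }
  } else {
    idx <- if (!is.null(names(fixed)) && any(names(fixed) %in% ff$labels)) {
      match(names(fixed), ff$labels)
    } else as.integer(names(fixed) %||% seq_along(fixed))
    if (any(is.na(idx))) stop("unknown fixed component", call. = FALSE)
    vfix <- as.numeric(fixed)
    fixed_mask[idx] <- TRUE
    if (all(fixed_mask)) {
      if (abs(sum(vfix) - 1) > 1e-9) stop("fixed fractions must sum to 1", call. = FALSE)
      profile <- Aw[, idx, drop = FALSE] %*% vfix
      scale_tot <- max(0, sum(profile * yw) / sum(profile^2))
      fractions[idx] <- vfix
    } else {
      vsum <- sum(vfix)
      if (vsum >= 1) stop("fixed fractions must sum to < 1", call. = FALSE)
      fixed_profile <- Aw[, idx, drop = FALSE] %*% vfix
      free <- which(!fixed_mask)
      # with S = sum(u) / (1 - vsum) the fixed part contributes
      # S * fixed_profile, so it folds into each free column:
      # model = sum_k u_k [I_k + fixed_profile / (1 - vsum)]
      Amod <- sweep(Aw[, free, drop = FALSE], 1L,
                    as.numeric(fixed_profile) / (1 - vsum), `+`)
      u <- nnls_solve(Amod, yw)
      total_u <- sum(u)
      if (total_u <= 0) {
        warning("degenerate fit: free component weights all zero", call. = FALSE)
        scale_tot <- 0
      } else {
        scale_tot <- total_u / (1 - vsum)
        fractions[free] <- u / scale_tot
        fractions[idx] <- vfix
      }
    }
  }
  resid <- yw - Aw %*% (fractions * scale_tot)
  chi2 <- sum(resid^2) / (length(yw) - 1L)
  structure(list(fractions = fractions, overall_scale = scale_tot,
                 chi2_reduced = chi2, fixed_mask = fixed_mask,
                 labels = ff$labels),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("mixture_fit: chi2_red =", format(x$chi2_reduced, digits = 4),
      " scale =", format(x$overall_scale, digits = 4), "\n")
  for (i in seq_along(x$fractions)) {
    cat(sprintf("  %-20s v = %.4f%s\n", x$labels[i], x$fractions[i],
                if (x$fixed_mask[i]) " (fixed)" else ""))
  }
  invisible(x)
}

#' Two-state decomposition of assembly/subcomplex equilibria
#'
#' Computes Debye intensities of a full multisubunit assembly and of a
#' specified subcomplex, then decomposes the experimental curve into the
#' two by \code{\link{fit_fractions}}. A warning is issued when the
#' estimated fraction of the dissociated species falls outside the
#' reliable window (about 0.15-0.90 for general subcomplexes; about
#' 0.2-0.8 for a monomer against its multimer).
#'
#' @param assembly full \code{\link{bead_model}}.
#' @param sub_selection chain id(s) or bead index vector selecting the
#'   subcomplex.
#' @param exp experimental \code{\link{saxs_curve}}.
#' @param reliable_range warning window for the dissociated-species
#'   fraction.
#' @param ... passed to \code{\link{debye_intensity}}.
#' @return a \code{mixture_fit} (component 1 = assembly, component 2 =
#'   subcomplex).
#' @export
two_state_decompose <- function(assembly, sub_selection, exp,
                                reliable_range = c(0.15, 0.90), ...) {
  stopifnot(inherits(assembly, "bead_model"))
  idx <- if (is.character(sub_selection)) {
    which(assembly$chain_id %in% sub_selection)
  } else as.integer(sub_selection)
  if (length(idx) == 0L) stop("empty subcomplex selection", call. = FALSE)
  if (length(idx) >= n_beads(assembly)) {
    stop("subcomplex must be a proper subset of the assembly", call. = FALSE)
  }
  sub <- bead_model(assembly$coords[idx, , drop = FALSE],
                    weight = assembly$weight[idx], radius = assembly$radius,
                    chain_id = assembly$chain_id[idx],
                    residue_index = assembly$residue_index[idx],
                    label = "subcomplex")
  full_lab <- if (nzchar(assembly$label)) assembly$label else "assembly"
  ff <- build_formfactors(list(assembly, sub), s_grid = exp$s,
                          labels = c(full_lab, "subcomplex"), ...)
  fit <- fit_fractions(ff, exp)
  v_sub <- fit$fractions[2L]
  if (v_sub > 1e-6 &&
      (v_sub < reliable_range[1] || v_sub > reliable_range[2])) {
    warning(sprintf("dissociated fraction %.2f outside the reliable window [%.2f, %.2f]",
                    v_sub, reliable_range[1], reliable_range[2]), call. = FALSE)
  }
  fit
}
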