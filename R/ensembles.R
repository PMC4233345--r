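# Ensemble selection for flexible systems: a genetic algorithm picks a
# variable-size multiset of pool members whose unweighted average curve
# fits the data, and the Rg distribution of the selected ensemble versus
# the pool diagnoses flexibility.

#' Bundle a pool of candidate theoretical curves
#'
#' @param curves list of \code{\link{saxs_curve}} objects on one common
#'   grid (M >= 10 for selection), or a \code{form_factor_set}.
#' @param rg optional per-member radius of gyration; computed by
#'   \code{\link{autorg}} on each member when missing.
#' @param labels optional member labels.
#' @return an object of class \code{curve_pool}.
#' @export
curve_pool <- function(curves, rg = NULL, labels = NULL) {
  if (inherits(curves, "form_factor_set")) {
    ff <- curves
    curves <- lapply(seq_len(ncol(ff$components)), function(k) {
      saxs_curve(ff$s, ff$components[, k], label = ff$labels[k])
    })
  }
  stopifnot(length(curves) >= 2L)
  s <- curves[[1L]]$s
  for (cu in curves) {
    if (length(cu$s) != length(s) || any(abs(cu$s - s) > 1e-9)) {
      stop("pool members must share one s grid", call. = FALSE)
    }
  }
  if (is.null(rg)) {
    rg <- vapply(curves, function(cu) {
      tryCatch(autorg(cu)$rg, error = function(e) NA_real_)
    }, numeric(1))
  }
  structure(list(s = s,
                 I = vapply(curves, function(cu) cu$I, numeric(length(s))),
                 rg = rg,
                 labels = labels %||% vapply(curves, function(cu) cu$label,
                                             character(1))),
            class = "curve_pool")
}

#' @export
print.curve_pool <- function(x, ...) {
  cat("curve_pool:", ncol(x$I), "members,",
      length(x$s), "grid points, Rg in [",
      format(min(x$rg, na.rm = TRUE), digits = 4), ",",
      format(max(x$rg, na.rm = TRUE), digits = 4), "] A\n")
  invisible(x)
}

#' Genetic-algorithm selection of a fitting sub-ensemble
#'
#' Evolves multisets of pool indices (chromosomes, variable size within
#' \code{size_bounds}; repeated members encode weight). The fitness of a
#' chromosome is the reduced chi-square of the unweighted average of its
#' member curves fitted to the data with a free scale (and optional
#' bounded constant) via \code{\link{fit_to_data}}. Operators: uniform
#' crossover of multisets, point mutation (replace a member), and size
#' mutation (insert or delete a member) which adjusts the chromosome size
#' automatically; elitism preserves the best \code{elite} chromosomes.
#'
#' @param pool a \code{\link{curve_pool}}.
#' @param exp experimental \code{\link{saxs_curve}} on a grid covered by
#'   the pool.
#' @param population chromosomes per generation.
#' @param generations maximum generations.
#' @param size_bounds integer length 2, chromosome size limits.
#' @param mutation_rate per-slot replacement probability.
#' @param size_mutation_rate probability of an insert/delete per offspring.
#' @param elite chromosomes carried over unchanged.
#' @param fit_constant allow a background constant in the fit.
#' @param plateau stop early after this many generations without
#'   improvement.
#' @param n_restarts independent GA runs (fresh initial populations);
#'   the best final chromosome wins. Restarts are the standard guard
#'   against the strong local optima of subset-selection landscapes.
#' @param seed RNG seed; fixed seeds give bit-identical solutions.
#' @return an \code{ensemble_solution}: list with \code{members} (selected
#'   index multiset), \code{chi2_reduced}, \code{rg_selected},
#'   \code{rg_pool}, \code{fit} and \code{generations_run}.
#' @export
select_ensemble <- function(pool, exp, population = 50L, generations = 200L,
                            size_bounds = c(5L, 50L), mutation_rate = 0.1,
                            size_mutation_rate = 0.2, elite = 2L,
                            fit_constant = FALSE, plateau = 50L,
                            n_restarts = 5L, seed = 1) {
  stopifnot(inherits(pool, "curve_pool"), inherits(exp, "saxs_curve"))
  m <- ncol(pool$I)
  if (m < size_bounds[1]) stop("pool smaller than the minimum ensemble size", call. = FALSE)
  if (m < 10L) stop("pool too small for selection (M >= 10)", call. = FALSE)
  set.seed(seed)
  pool_I <- apply(pool$I, 2L, function(col)
    interp_curve_values(pool$s, col, exp$s))
  wts <- if (!is.null(exp$sigma)) 1 / exp$sigma^2 else rep(1, length(exp$s))
  b_bounds <- if (fit_constant) c(-0.1, 0.1) * max(abs(exp$I)) else c(0, 0)
  fitness <- function(chrom) {
    avg <- rowMeans(pool_I[, chrom, drop = FALSE])
    p <- fit_scale_background(avg, exp$I, wts, b_bounds[1], b_bounds[2])
    sum(wts * (exp$I - p[1] * avg - p[2])^2) / (length(exp$s) - 1L)
  }
  rand_chrom <- function() {
    sz <- sample(size_bounds[1]:min(size_bounds[2], m), 1L)
    sample.int(m, sz, replace = TRUE)
  }
  # NNLS decomposition of the data against the whole pool: its support is
  # sparse, so chromosomes built from it seed the search near parsimonious
  # solutions that a purely random population rarely visits
  nnls_w <- tryCatch({
    sg <- if (!is.null(exp$sigma)) exp$sigma else rep(1, length(exp$I))
    pracma::lsqnonneg(pool_I / sg, exp$I / sg)$x
  }, error = function(e) NULL)
  nnls_chrom <- function() {
    if (is.null(nnls_w) || sum(nnls_w) <= 0) return(rand_chrom())
    p <- nnls_w / sum(nnls_w)
    sz <- sample(seq.int(size_bounds[1], min(size_bounds[2], 4L * size_bounds[1])), 1L)
    sort(sample.int(m, sz, replace = TRUE, prob = p + 1e-6))
  }
  run_ga <- function() {
  # greedy single-member refinement of a chromosome: try deleting each
  # member and replacing each member with a random alternative, keeping
  # improvements; sharpens the elite without touching population diversity
  local_refine <- function(chrom, chi) {
    for (pos in sample.int(length(chrom))) {
      if (length(chrom) > size_bounds[1]) {
        cand <- chrom[-pos]
        chi_c <- fitness(cand)
        if (chi_c < chi) { chrom <- cand; chi <- chi_c; next }
      }
      if (pos <= length(chrom)) {
        cand <- chrom
        cand[pos] <- sample.int(m, 1L)
        chi_c <- fitness(cand)
        if (chi_c < chi) { chrom <- cand; chi <- chi_c }
      }
      if (pos <= length(chrom) && length(chrom) > 1L) {
        # re-balance multiplicities: overwrite with another current member
        cand <- chrom
        cand[pos] <- sample(chrom[-pos], 1L)
        chi_c <- fitness(cand)
        if (chi_c < chi) { chrom <- cand; chi <- chi_c }
      }
    }
    list(chrom = chrom, chi = chi)
  }
  popn <- c(replicate(ceiling(population / 5), nnls_chrom(), simplify = FALSE),
            replicate(population - ceiling(population / 5), rand_chrom(),
                      simplify = FALSE))
  fit_vals <- vapply(popn, fitness, numeric(1))
  best_chi <- Inf; stale <- 0L; gens_run <- 0L
  for (g in seq_len(generations)) {
    gens_run <- g
    ord <- order(fit_vals)
    popn <- popn[ord]; fit_vals <- fit_vals[ord]
    ref <- local_refine(popn[[1L]], fit_vals[1L])
    popn[[1L]] <- ref$chrom; fit_vals[1L] <- ref$chi
    if (fit_vals[1] < best_chi - 1e-12) { best_chi <- fit_vals[1]; stale <- 0L }
    else stale <- stale + 1L
    if (stale >= plateau || best_chi < 1e-12) break
    if (stale > 0L && stale %% 20L == 0L) {
      # stagnation: re-seed the bottom half to restore diversity
      lower <- (population %/% 2L):population
      popn[lower] <- replicate(length(lower), rand_chrom(), simplify = FALSE)
      fit_vals[lower] <- vapply(popn[lower], fitness, numeric(1))
    }
    newpop <- popn[seq_len(elite)]
    # tournament selection
    pick_parent <- function() {
      cand <- sample.int(population, 2L)
      popn[[cand[which.min(fit_vals[cand])]]]
    }
    while (length(newpop) < population) {
      pa <- pick_parent(); pb <- pick_parent()
      merged <- c(pa, pb)
      take <- stats::runif(length(merged)) < 0.5
      child <- merged[take]
      if (length(child) < size_bounds[1]) {
        child <- sample(merged, size_bounds[1], replace = TRUE)
      }
      if (length(child) > size_bounds[2]) {
        child <- child[sample.int(length(child), size_bounds[2])]
      }
      mut <- stats::runif(length(child)) < mutation_rate
      child[mut] <- sample.int(m, sum(mut), replace = TRUE)
      if (stats::runif(1) < size_mutation_rate) {
        if (stats::runif(1) < 0.5 && length(child) < size_bounds[2]) {
          child <- c(child, sample.int(m, 1L))
        } else if (length(child) > size_bounds[1]) {
          child <- child[-sample.int(length(child), 1L)]
        }
      }
      newpop[[length(newpop) + 1L]] <- child
    }
    popn <- newpop
    fit_vals <- vapply(popn, fitness, numeric(1))
  }
  ord <- order(fit_vals)
  list(chrom = popn[[ord[1L]]], chi = fit_vals[ord[1L]],
       gens = gens_run)
  }
  best <- NULL
  total_gens <- 0L
  for (r in seq_len(max(1L, n_restarts))) {
    run <- run_ga()
    total_gens <- total_gens + run$gens
    if (is.null(best) || run$chi < best$chi) best <- run
    if (best$chi < 1e-12) break
  }
  best <- best$chrom
  avg <- rowMeans(pool_I[, best, drop = FALSE])
  p <- fit_scale_background(avg, exp$I, wts, b_bounds[1], b_bounds[2])
  fitted <- exp
  fitted$I_fit <- p[1] * avg + p[2]
  final_chi <- sum(wts * (exp$I - fitted$I_fit)^2) / (length(exp$s) - 1L)
  structure(list(members = sort(best), chi2_reduced = final_chi,
                 rg_selected = pool$rg[best], rg_pool = pool$rg,
                 scale_c = p[1], background = p[2], fitted_curve = fitted,
                 generations_run = total_gens),
            class = "ensemble_solution")
}

#' @export
print.ensemble_solution <- function(x, ...) {
  cat(sprintf("ensemble_solution: %d members (%d distinct), chi2_red = %.4g, %d generations\n",
              length(x$members), length(unique(x$members)), x$chi2_reduced,
              x$generations_run))
  invisible(x)
}

#' Flexibility verdict from the selected-versus-pool Rg distributions
#'
#' A selected ensemble whose Rg distribution is as broad as the pool's
#' indicates a flexible system; a much narrower distribution indicates a
#' rigid one. The verdict compares the Rg variance ratio
#' (selected / pool): \code{flexible} when >= \code{flexible_ratio},
#' \code{rigid} when <= \code{rigid_ratio}, otherwise
#' \code{indeterminate}. The mean-Rg shift reports compaction or
#' extension relative to the pool.
#'
#' @param solution an \code{ensemble_solution}.
#' @param flexible_ratio,rigid_ratio verdict thresholds on the variance
#'   ratio.
#' @return list with \code{verdict}, \code{variance_ratio},
#'   \code{mean_shift} (Angstrom, selected minus pool) and
#'   \code{direction} (\code{"compact"}, \code{"extended"} or
#'   \code{"unshifted"}).
#' @export
flexibility_report <- function(solution, flexible_ratio = 0.8,
                               rigid_ratio = 0.3) {
  stopifnot(inherits(solution, "ensemble_solution"))
  rg_sel <- solution$rg_selected[is.finite(solution$rg_selected)]
  rg_pool <- solution$rg_pool[is.finite(solution$rg_pool)]
  v_pool <- stats::var(rg_pool)
  v_sel <- if (length(rg_sel) > 1L) stats::var(rg_sel) else 0
  ratio <- if (isTRUE(v_pool > 0)) v_sel / v_pool else NA_real_
  verdict <- if (!is.finite(ratio)) "indeterminate"
  else if (ratio >= flexible_ratio) "flexible"
  else if (ratio <= rigid_ratio) "rigid"
  else "indeterminate"
  shift <- mean(rg_sel) - mean(rg_pool)
  spread <- stats::sd(rg_pool)
  direction <- if (!is.finite(shift) || !isTRUE(spread > 0) ||
                   abs(shift) < 0.1 * spread) "unshifted"
  else if (shift < 0) "compact" else "extended"
  list(verdict = verdict, variance_ratio = ratio, mean_shift = shift,
       direction = direction)
}
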