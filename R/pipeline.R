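# Pipeline driver: runs a flat list of tool stages with file bindings so
# that the output of one stage feeds the input of the next, as in
# automated beamline processing chains. Each stage emits one
# machine-readable report.

#' @noRd
pipeline_tools <- function() {
  list(
    simulate = function(args) {
      body <- args$body %||% "sphere"
      s_grid <- seq(args$s_min %||% 0.005, args$s_max %||% 0.5,
                    length.out = args$n_points %||% 200L)
      cur <- analytic_curve(body, s_grid,
                            radius = args$radius %||% 30,
                            semi_axes = unlist(args$semi_axes %||% c(20, 20, 60)),
                            rg = args$rg %||% 20, i0 = args$i0 %||% 1000)
      if (!is.null(args$noise_relative)) {
        if (is.null(args$seed)) stop("randomized stage requires a seed", call. = FALSE)
        cur <- apply_noise(cur, noise_model(relative = args$noise_relative),
                           seed = args$seed)
      }
      write_curve(cur, args$output)
      list(output = args$output, n_points = length(cur$s))
    },
    autorg = function(args) {
      g <- autorg(read_curve(args$input))
      unclass(g)
    },
    autoporod = function(args) {
      res <- autoporod(read_curve(args$input))
      res$guinier <- unclass(res$guinier)
      unclass(res)
    },
    datcmp = function(args) {
      curve_compare(read_curve(args$input), read_curve(args$input2))
    },
    merge = function(args) {
      merged <- curve_merge(read_curve(args$input), read_curve(args$input2))
      write_curve(merged, args$output)
      list(output = args$output, n_points = length(merged$s))
    }
  )
}

#' Run a multi-stage processing pipeline
#'
#' The configuration is a list (or JSON file) of stages
#' \code{list(tool = "...", args = list(...))}; known tools are
#' \code{simulate}, \code{autorg}, \code{autoporod}, \code{datcmp} and
#' \code{merge}. The whole configuration is validated before anything
#' runs: unknown tools and missing input files abort with a config error.
#' Stages run in order; by default the first stage error stops the run.
#' Chained stages are exactly equivalent to calling the underlying
#' functions by hand with the same parameters.
#'
#' @param config list of stages, or path to a JSON file holding one.
#' @param keep_going continue past failed stages.
#' @return list of per-stage reports (tool, parameters, result or error);
#'   an empty configuration yields an empty report list.
#' @export
run_pipeline <- function(config, keep_going = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = FALSE)
  }
  stopifnot(is.list(config))
  tools <- pipeline_tools()
  if (length(config) == 0L) return(list())
  # pre-flight validation before any stage executes
  produced <- character(0)
  for (i in seq_along(config)) {
    st <- config[[i]]
    if (is.null(st$tool) || !st$tool %in% names(tools)) {
      stop("config error in stage ", i, ": unknown tool '",
           st$tool %||% "<missing>", "'", call. = FALSE)
    }
    for (f in unlist(st$args[c("input", "input2")])) {
      if (!is.null(f) && !file.exists(f) && !(f %in% produced)) {
        stop("config error in stage ", i, ": missing input file '", f, "'",
             call. = FALSE)
      }
    }
    if (!is.null(st$args$output)) produced <- c(produced, st$args$output)
  }
  reports <- vector("list", length(config))
  for (i in seq_along(config)) {
    st <- config[[i]]
    res <- tryCatch(
      list(tool = st$tool, args = st$args, status = "ok",
           result = tools[[st$tool]](st$args)),
      error = function(e) list(tool = st$tool, args = st$args,
                               status = "error",
                               message = conditionMessage(e)))
    reports[[i]] <- res
    if (identical(res$status, "error") && !keep_going) {
      return(reports[seq_len(i)])
    }
  }
  reports
}
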