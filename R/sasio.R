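# File I/O: ASCII scattering curves (.dat/.fit), PDB coordinate models
# (via bio3d), MRC/CCP4 density maps.

#' Read a 1-D scattering curve from a text file
#'
#' Parses whitespace-separated columns \code{s I [sigma [I_fit]]}. Leading
#' and trailing non-numeric lines are tolerated; the first non-numeric
#' leading line becomes the curve label. Rows with negative intensity are
#' kept (buffer-subtracted data may dip below zero); rows with \code{s < 0}
#' or \code{sigma <= 0} are rejected.
#'
#' @param path path to a 2-, 3- or 4-column ASCII file.
#' @param format_hint optional, one of \code{"dat"} or \code{"fit"}; by
#'   default the layout is inferred from the column count (4 columns are
#'   read as \code{s, I, sigma, I_fit}).
#' @param unit unit of the s column, \code{"A"} or \code{"nm"}.
#' @return a \code{\link{saxs_curve}}; for 4-column fit files the fitted
#'   intensities are attached as \code{$I_fit}.
#' @export
read_curve <- function(path, format_hint = NULL, unit = "A") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  numeric_row <- function(tk) {
    length(tk) >= 2L && !any(is.na(suppressWarnings(as.numeric(tk))))
  }
  is_num <- vapply(toks, numeric_row, logical(1)) & nzchar(trimws(lines))
  if (!any(is_num)) {
    first_bad <- which(nzchar(trimws(lines)))[1] %||% 1L
    stop("no numeric data rows in ", path, "; first line: ",
         lines[first_bad], call. = FALSE)
  }
  # contiguous numeric block: header above, footer below
  idx <- range(which(is_num))
  block <- idx[1]:idx[2]
  bad_inside <- block[!is_num[block]]
  if (length(bad_inside) > 0L) {
    stop("unparseable line inside data block: '", lines[bad_inside[1]], "'",
         call. = FALSE)
  }
  header <- trimws(lines[seq_len(idx[1] - 1L)])
  header <- header[nzchar(header)]
  ncols <- lengths(toks[block])
  ncol_use <- min(ncols)
  vals <- t(vapply(toks[block],
                   function(tk) as.numeric(tk[seq_len(ncol_use)]),
                   numeric(ncol_use)))
  s <- vals[, 1L]
  bad <- s < 0
  if (ncol_use >= 3L) bad <- bad | vals[, 3L] <= 0
  vals <- vals[!bad, , drop = FALSE]
  s <- vals[, 1L]; I <- vals[, 2L]
  if (any(diff(s) <= 0)) {
    stop("s column is not strictly increasing in ", path, call. = FALSE)
  }
  sigma <- if (ncol_use >= 3L) vals[, 3L] else NULL
  cur <- saxs_curve(s, I, sigma, label = if (length(header)) header[1] else "",
                    unit = unit)
  if (ncol_use >= 4L || identical(format_hint, "fit")) {
    if (ncol_use >= 4L) cur$I_fit <- vals[, 4L]
  }
  cur
}

#' Write a scattering curve to a text file
#'
#' Columns \code{s I [sigma [I_fit]]} at 8 significant digits; a label, when
#' present, is written as a first header line. \code{read_curve} round-trips
#' the numeric content to better than 1e-6 relative.
#'
#' @param curve a \code{\link{saxs_curve}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_curve <- function(curve, path) {
  stopifnot(inherits(curve, "saxs_curve"))
  cols <- list(curve$s, curve$I)
  if (!is.null(curve$sigma)) cols <- c(cols, list(curve$sigma))
  if (!is.null(curve$I_fit) && !is.null(curve$sigma)) {
    cols <- c(cols, list(curve$I_fit))
  }
  mat <- do.call(cbind, lapply(cols, function(v) sprintf("%.8e", v)))
  con <- file(path, "w")
  on.exit(close(con))
  if (nzchar(curve$label %||% "")) writeLines(curve$label, con)
  writeLines(apply(mat, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' Read a coordinate model from a PDB file
#'
#' Thin wrapper around \code{bio3d::read.pdb} that normalises coordinates
#' into \code{\link{bead_model}} objects.
#'
#' @param path PDB file path.
#' @param mode \code{"ca_only"} keeps CA records in chain/residue order;
#'   \code{"full_atom"} keeps all ATOM/HETATM records; \code{"bead"} treats
#'   every ATOM as a dummy bead with uniform weight.
#' @param keep_hydrogens keep H atoms (default drops them; set \code{TRUE}
#'   to take all atoms as deposited).
#' @param multi when the file holds several MODEL blocks (e.g. an NMR
#'   ensemble) return a list of one model per block.
#' @param weight,radius passed to \code{\link{bead_model}}.
#' @return a \code{bead_model}, or a list of them when \code{multi = TRUE}
#'   and the file holds several MODEL blocks.
#' @export
read_model <- function(path, mode = c("ca_only", "full_atom", "bead"),
                       keep_hydrogens = FALSE, multi = FALSE,
                       weight = 1, radius = 1.9) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  pdb <- bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  if (!keep_hydrogens) {
    elt <- toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                 substr(trimws(at$elety), 1, 1), at$elesy)))
    keep <- keep & elt != "H" & elt != "D"
  }
  if (mode == "ca_only") keep <- keep & toupper(trimws(at$elety)) == "CA"
  if (!any(keep)) stop("no usable ATOM records in ", path, call. = FALSE)
  build <- function(xyz) {
    m <- matrix(xyz, ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
    bead_model(m, weight = weight, radius = radius,
               chain_id = at$chain[keep],
               residue_index = at$resno[keep],
               label = basename(path))
  }
  nmod <- if (is.matrix(pdb$xyz)) nrow(pdb$xyz) else 1L
  if (multi && nmod > 1L) {
    lapply(seq_len(nmod), function(k) build(pdb$xyz[k, ]))
  } else {
    build(if (is.matrix(pdb$xyz)) pdb$xyz[1L, ] else pdb$xyz)
  }
}

#' Write a bead model as PDB-like dummy-atom records
#'
#' @param model a \code{\link{bead_model}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "bead_model"))
  n <- n_beads(model)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(model$coords)),
                   resno = model$residue_index,
                   chain = model$chain_id,
                   resid = rep("DUM", n),
                   elety = rep("CA", n),
                   o = rep(1, n), b = model$weight)
  invisible(path)
}

# ---- MRC/CCP4 density maps -------------------------------------------------
# Minimal reader for mode-2 (float32) maps. Axis order is normalised to
# x,y,z using the MAPC/MAPR/MAPS header words.

#' Read an MRC/CCP4 density map
#'
#' Supports mode 2 (32-bit float) maps; grid dimensions, voxel size and
#' origin are taken from the header and the axis order is normalised to
#' x, y, z.
#'
#' @param path map file path.
#' @return a \code{\link{density_grid}}.
#' @export
read_density <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr_int <- readBin(con, "integer", n = 10L, size = 4L, endian = "little")
  if (length(hdr_int) < 10L) stop("corrupt map header: file too short", call. = FALSE)
  nc <- hdr_int[1]; nr <- hdr_int[2]; ns <- hdr_int[3]; mode <- hdr_int[4]
  if (any(c(nc, nr, ns) <= 0) || any(c(nc, nr, ns) > 1e4) || mode != 2L) {
    stop("corrupt or unsupported map header (need mode-2 MRC/CCP4)", call. = FALSE)
  }
  hdr_f1 <- readBin(con, "numeric", n = 6L, size = 4L, endian = "little")  # cell a,b,c + angles
  mx <- hdr_int[8]; my <- hdr_int[9]; mz <- hdr_int[10]
  axis_map <- readBin(con, "integer", n = 3L, size = 4L, endian = "little") # words 17-19 MAPC/R/S
  invisible(readBin(con, "numeric", n = 3L, size = 4L, endian = "little"))  # dmin,dmax,dmean
  invisible(readBin(con, "integer", n = 2L, size = 4L, endian = "little"))  # ispg, nsymbt
  invisible(readBin(con, "raw", n = 100L))                                  # extra incl. words 25-49
  origin <- readBin(con, "numeric", n = 3L, size = 4L, endian = "little")   # words 50-52
  invisible(readBin(con, "raw", n = 1024L - 4L * 52L))
  nvox <- nc * nr * ns
  vals <- readBin(con, "numeric", n = nvox, size = 4L, endian = "little")
  if (length(vals) < nvox) stop("map file truncated mid-data", call. = FALSE)
  arr <- array(vals, dim = c(nc, nr, ns))
  if (!all(sort(axis_map) == 1:3)) axis_map <- 1:3
  perm <- order(axis_map)          # permutation taking (col,row,sec) -> (x,y,z)
  arr <- aperm(arr, perm)
  mgrid <- c(mx, my, mz)
  cell <- hdr_f1[1:3]
  voxel <- ifelse(mgrid > 0 & cell > 0, cell / mgrid, 1)
  density_grid(arr, voxel_size = voxel, origin = origin)
}

#' Write an MRC-format density map (mode 2)
#'
#' Counterpart of \code{\link{read_density}}, used mainly to build test
#' inputs and to export thresholded grids.
#'
#' @param grid a \code{\link{density_grid}}.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_density <- function(grid, path) {
  stopifnot(inherits(grid, "density_grid"))
  d <- dim(grid$values)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L, 0L, 0L, 0L, d)), con, size = 4L, endian = "little")
  writeBin(as.numeric(c(d * grid$voxel_size, 90, 90, 90)), con, size = 4L,
           endian = "little")
  writeBin(1:3, con, size = 4L, endian = "little")
  v <- grid$values
  writeBin(as.numeric(c(min(v), max(v), mean(v))), con, size = 4L, endian = "little")
  writeBin(c(1L, 0L), con, size = 4L, endian = "little")
  writeBin(raw(100L), con)
  writeBin(as.numeric(grid$origin), con, size = 4L, endian = "little")
  writeBin(raw(1024L - 4L * 52L), con)
  writeBin(as.numeric(v), con, size = 4L, endian = "little")
  invisible(path)
}
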