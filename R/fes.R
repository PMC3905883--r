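## Free-energy-surface reconstruction from deposited Gaussian hills on a
## rectangular CV grid, with the unbinding stop criterion.

#' Rectangular CV grid specification
#'
#' @param min,max per-CV lower/upper bounds (numeric, one entry per CV).
#' @param n_points nodes per CV axis (>= 2 each; default 500 per axis).
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(min, max, n_points = 500L) {
  d <- length(min)
  stopifnot(length(max) == d)
  if (length(n_points) == 1L) n_points <- rep(n_points, d)
  n_points <- as.integer(n_points)
  if (any(max <= min)) stop("grid 'max' must exceed 'min' on every axis")
  if (any(n_points < 2L)) stop("grid needs >= 2 points per axis")
  structure(list(min = as.numeric(min), max = as.numeric(max),
                 n_points = n_points),
            class = "grid_spec")
}

.grid_axes <- function(spec) {
  lapply(seq_along(spec$min), function(k)
    seq(spec$min[k], spec$max[k], length.out = spec$n_points[k]))
}

#' Default grid bounds for a hill list
#'
#' Bounding box of the hill centers padded by `pad_sigmas` hill widths on
#' each side.
#'
#' @param hills hills data frame.
#' @param n_points nodes per axis.
#' @param pad_sigmas padding in units of the maximum hill width (default 3).
#' @return A [grid_spec()].
#' @export
grid_spec_for_hills <- function(hills, n_points = 500L, pad_sigmas = 3) {
  d <- .hills_dim(hills)
  ctr <- .hills_centers(hills, d)
  sig <- .hills_sigmas(hills, d)
  pad <- pad_sigmas * apply(sig, 2L, max)
  grid_spec(apply(ctr, 2L, min) - pad, apply(ctr, 2L, max) + pad, n_points)
}

#' Reconstruct the free-energy surface from deposited hills
#'
#' The FES is the negated sum of the deposited Gaussian hills evaluated at
#' every grid node (exact summation, no tail truncation), scaled by
#' `gamma / (gamma - 1)` in well-tempered mode, then shifted so the global
#' minimum is zero.
#'
#' @param hills hills data frame with >= 1 hill.
#' @param spec a [grid_spec()]; default from [grid_spec_for_hills()].
#' @param mode `"standard"` or `"well_tempered"`.
#' @param bias_factor gamma (> 1), used in well-tempered mode only; if
#'   missing, taken from the hills' `biasf` column.
#' @return An object of class `fes_grid`: `spec`, `axes`, `values` (matrix
#'   `n1 x n2`, or a vector in 1-D; kJ/mol, min = 0) and `offset` (the
#'   subtracted shift).
#' @export
reconstruct_fes <- function(hills, spec = NULL,
                            mode = c("standard", "well_tempered"),
                            bias_factor = NULL) {
  mode <- match.arg(mode)
  if (nrow(hills) == 0L) stop("empty hill list")
  d <- .hills_dim(hills)
  if (is.null(spec)) spec <- grid_spec_for_hills(hills)
  stopifnot(inherits(spec, "grid_spec"), length(spec$min) == d)
  axes <- .grid_axes(spec)
  bias <- .sum_hills_grid(.hills_centers(hills, d), .hills_sigmas(hills, d),
                          hills$height, axes)
  f <- -bias
  if (mode == "well_tempered") {
    if (is.null(bias_factor)) {
      bias_factor <- unique(hills$biasf)
      if (length(bias_factor) != 1L)
        stop("hills carry multiple bias factors; pass 'bias_factor'")
    }
    if (bias_factor <= 1) stop("'bias_factor' must be > 1")
    f <- f * bias_factor / (bias_factor - 1)
  }
  offset <- min(f)
  f <- f - offset
  if (d == 2L) dim(f) <- spec$n_points
  structure(list(spec = spec, axes = axes, values = f, offset = offset,
                 mode = mode),
            class = "fes_grid")
}

#' @export
print.fes_grid <- function(x, ...) {
  cat("<fes_grid>", paste(x$spec$n_points, collapse = " x "),
      sprintf("nodes, range 0 .. %.3g kJ/mol (%s)\n",
              max(x$values), x$mode))
  invisible(x)
}

#' Interpolate a free-energy surface at arbitrary CV points
#'
#' Bilinear (linear in 1-D) interpolation; points outside the grid return
#' `NA`.
#'
#' @param fes an `fes_grid`.
#' @param x numeric vector (one point) or matrix of points in rows.
#' @return Free energies, kJ/mol.
#' @export
fes_interpolate <- function(fes, x) {
  d <- length(fes$spec$min)
  x <- .as_points(x, d)
  ax1 <- fes$axes[[1L]]
  out <- rep(NA_real_, nrow(x))
  inside <- x[, 1L] >= fes$spec$min[1L] & x[, 1L] <= fes$spec$max[1L]
  if (d == 2L)
    inside <- inside & x[, 2L] >= fes$spec$min[2L] &
      x[, 2L] <= fes$spec$max[2L]
  if (!any(inside)) return(out)
  xi <- x[inside, , drop = FALSE]
  h1 <- ax1[2L] - ax1[1L]
  i0 <- pmin.int(pmax.int(floor((xi[, 1L] - ax1[1L]) / h1) + 1L, 1L),
                 length(ax1) - 1L)
  wx <- (xi[, 1L] - ax1[i0]) / h1
  if (d == 1L) {
    v <- fes$values
    out[inside] <- v[i0] * (1 - wx) + v[i0 + 1L] * wx
    return(out)
  }
  ax2 <- fes$axes[[2L]]
  h2 <- ax2[2L] - ax2[1L]
  j0 <- pmin.int(pmax.int(floor((xi[, 2L] - ax2[1L]) / h2) + 1L, 1L),
                 length(ax2) - 1L)
  wy <- (xi[, 2L] - ax2[j0]) / h2
  v <- fes$values
  out[inside] <-
    v[cbind(i0, j0)] * (1 - wx) * (1 - wy) +
    v[cbind(i0 + 1L, j0)] * wx * (1 - wy) +
    v[cbind(i0, j0 + 1L)] * (1 - wx) * wy +
    v[cbind(i0 + 1L, j0 + 1L)] * wx * wy
  out
}

#' Smooth a free-energy surface at the hill-width resolution
#'
#' Separable Gaussian filter on the grid values, with edge renormalisation.
#' A metadynamics FES carries no information below the deposited hill
#' width, so filtering at that scale removes the deposition sawtooth while
#' leaving genuine basins (much wider than a hill) intact; minima counting
#' and basin labelling on reconstructed surfaces use the smoothed surface.
#'
#' @param fes an `fes_grid`.
#' @param sigma per-CV smoothing width in CV units (e.g. the hill widths).
#' @return A smoothed `fes_grid` (re-shifted so the minimum is 0).
#' @export
fes_smooth <- function(fes, sigma) {
  d <- length(fes$spec$min)
  if (length(sigma) == 1L) sigma <- rep(sigma, d)
  stopifnot(length(sigma) == d, all(sigma >= 0))
  kern_mat <- function(axis, s) {
    n <- length(axis)
    if (s <= 0) return(diag(n))
    h <- axis[2L] - axis[1L]
    half <- max(1L, ceiling(4 * s / h))
    offs <- (-half):half
    w <- exp(-0.5 * (offs * h / s)^2)
    k <- matrix(0, n, n)
    for (o in seq_along(offs)) {
      j <- seq_len(n) + offs[o]
      ok <- j >= 1L & j <= n
      k[cbind(which(ok), j[ok])] <- w[o]
    }
    k / rowSums(k)
  }
  v <- fes$values
  if (d == 1L) {
    v <- as.numeric(kern_mat(fes$axes[[1L]], sigma[1L]) %*% v)
  } else {
    v <- kern_mat(fes$axes[[1L]], sigma[1L]) %*% v %*%
      t(kern_mat(fes$axes[[2L]], sigma[2L]))
  }
  off <- min(v)
  structure(list(spec = fes$spec, axes = fes$axes, values = v - off,
                 offset = fes$offset + off, mode = fes$mode),
            class = "fes_grid")
}

#' Time-averaged free-energy surface estimate
#'
#' For standard (non-tempered) metadynamics the instantaneous negated hill
#' sum oscillates around the free energy once the basins are filled;
#' averaging the pre-shift estimate over deposition time removes most of
#' that sawtooth noise.  This computes the average of the cumulative-hill
#' FES over `n_checkpoints` evenly spaced checkpoints between
#' `start_fraction` of the run and its end, then shifts the global minimum
#' to zero.
#'
#' @param hills hills data frame.
#' @param spec a [grid_spec()]; default from [grid_spec_for_hills()].
#' @param start_fraction first checkpoint as a fraction of the hill count
#'   (default 0.5: average over the last half of the deposition).
#' @param n_checkpoints number of checkpoints averaged (default 40).
#' @return An `fes_grid` (minimum 0).
#' @export
fes_time_average <- function(hills, spec = NULL, start_fraction = 0.5,
                             n_checkpoints = 40L) {
  if (nrow(hills) == 0L) stop("empty hill list")
  stopifnot(start_fraction > 0, start_fraction <= 1, n_checkpoints >= 1L)
  d <- .hills_dim(hills)
  if (is.null(spec)) spec <- grid_spec_for_hills(hills)
  axes <- .grid_axes(spec)
  n <- nrow(hills)
  cks <- unique(round(seq(max(1, start_fraction * n), n,
                          length.out = n_checkpoints)))
  m <- length(cks)
  ## average of cumulative sums = weighted sum over hill chunks: the chunk
  ## ending at checkpoint j contributes to checkpoints j..m
  acc <- 0
  prev <- 0L
  for (j in seq_along(cks)) {
    idx <- seq(prev + 1L, cks[j])
    chunk <- .sum_hills_grid(.hills_centers(hills, d)[idx, , drop = FALSE],
                             .hills_sigmas(hills, d)[idx, , drop = FALSE],
                             hills$height[idx], axes)
    acc <- acc + chunk * (m - j + 1L) / m
    prev <- cks[j]
  }
  f <- -acc
  offset <- min(f)
  f <- f - offset
  if (d == 2L) dim(f) <- spec$n_points
  structure(list(spec = spec, axes = axes, values = f, offset = offset,
                 mode = "standard"),
            class = "fes_grid")
}

#' Truncate a hill list at the unbinding escape time
#'
#' Keeps the hills deposited up to the first time the distance CV reaches
#' the reference threshold (default 4.0 nm, the point at which the ligand
#' no longer contacts the complex); all hills are kept if the threshold is
#' never reached.
#'
#' @param colvar data frame with columns `time` and the distance CV (first
#'   CV column).
#' @param hills hills data frame sharing the time axis.
#' @param distance_threshold nm (> 0).
#' @param distance_col name of the distance column (default: first non-time
#'   column).
#' @return The truncated hills data frame.
#' @export
truncate_at_escape <- function(colvar, hills, distance_threshold = 4.0,
                               distance_col = NULL) {
  if (!is.numeric(distance_threshold) || distance_threshold <= 0)
    stop("'distance_threshold' must be > 0")
  stopifnot("time" %in% names(colvar))
  if (is.null(distance_col))
    distance_col <- setdiff(names(colvar), "time")[1L]
  dist <- colvar[[distance_col]]
  hit <- which(dist >= distance_threshold)
  if (length(hit) == 0L) return(hills)
  t_escape <- colvar$time[hit[1L]]
  hills[hills$time <= t_escape, , drop = FALSE]
}

#' Write a free-energy surface as plain text
#'
#' Three-column (`cv1 cv2 F`; two in 1-D) whitespace-delimited text in
#' grid-major order (first axis fastest) with a `#! FIELDS` header.
#'
#' @param fes an `fes_grid`.
#' @param path output file.
#' @export
write_fes <- function(fes, path) {
  d <- length(fes$spec$min)
  con <- file(path, "w")
  on.exit(close(con))
  if (d == 1L) {
    writeLines("#! FIELDS cv1 free_energy", con)
    tab <- data.frame(cv1 = fes$axes[[1L]], f = as.numeric(fes$values))
  } else {
    writeLines("#! FIELDS cv1 cv2 free_energy", con)
    g <- expand.grid(cv1 = fes$axes[[1L]], cv2 = fes$axes[[2L]],
                     KEEP.OUT.ATTRS = FALSE)
    tab <- cbind(g, f = as.numeric(fes$values))
  }
  write.table(format(tab, digits = 12, scientific = FALSE, trim = TRUE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a free-energy surface written by [write_fes()]
#'
#' @param path input file.
#' @return An `fes_grid`.
#' @export
read_fes <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^#!\\s*FIELDS", header)) stop("not a FES file: ", path)
  tab <- read.table(path, header = FALSE, comment.char = "#")
  d <- ncol(tab) - 1L
  axes <- lapply(seq_len(d), function(k) sort(unique(tab[[k]])))
  n <- vapply(axes, length, integer(1L))
  spec <- grid_spec(vapply(axes, min, numeric(1L)),
                    vapply(axes, max, numeric(1L)), n)
  vals <- tab[[d + 1L]]
  if (d == 2L) dim(vals) <- n
  structure(list(spec = spec, axes = axes, values = vals,
                 offset = NA_real_, mode = "standard"),
            class = "fes_grid")
}
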