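## Metadynamics engine: Gaussian hill bookkeeping, bias evaluation, and
## Langevin (BAOAB) sampling on toy potentials with on-the-fly hill
## deposition (standard or well-tempered).

#' Metadynamics parameters
#'
#' @param height initial Gaussian hill height w0, kJ/mol (> 0; the
#'   production default of 1.0 kJ/mol).
#' @param widths per-CV Gaussian sigma, in CV units (> 0).
#' @param pace time between hill depositions, ps (> 0; default 0.5 ps,
#'   i.e. one hill every 250 frames of 2 fs).
#' @param mode `"standard"` (constant heights) or `"well_tempered"`
#'   (heights decay with the accumulated local bias).
#' @param bias_factor well-tempered bias factor gamma (> 1).
#' @param temperature K (used by the well-tempered damping).
#' @return An object of class `meta_params`.
#' @export
meta_params <- function(height = 1.0, widths = 0.05, pace = 0.5,
                        mode = c("standard", "well_tempered"),
                        bias_factor = 10, temperature = 300) {
  mode <- match.arg(mode)
  if (!is.numeric(height) || height <= 0) stop("'height' must be > 0")
  if (any(widths <= 0)) stop("'widths' must be > 0")
  if (pace <= 0) stop("'pace' must be > 0")
  if (mode == "well_tempered" && bias_factor <= 1)
    stop("'bias_factor' must be > 1 in well-tempered mode")
  structure(list(height = height, widths = as.numeric(widths), pace = pace,
                 mode = mode, bias_factor = bias_factor,
                 temperature = temperature),
            class = "meta_params")
}

#' Height of the next deposited hill
#'
#' Standard metadynamics deposits constant-height hills; the well-tempered
#' variant damps the height exponentially with the bias already accumulated
#' at the deposition point: `w0 * exp(-V / (kB * (gamma - 1) * T))`.
#'
#' @param params a [meta_params()].
#' @param v_current bias already deposited at the current CV point, kJ/mol
#'   (>= 0).
#' @return Hill height in kJ/mol.
#' @export
next_hill_height <- function(params, v_current = 0) {
  stopifnot(inherits(params, "meta_params"))
  if (any(v_current < 0)) stop("'v_current' must be >= 0")
  if (params$mode == "standard") return(rep(params$height,
                                            length(v_current)))
  if (params$bias_factor <= 1)
    stop("'bias_factor' must be > 1 in well-tempered mode")
  params$height *
    exp(-v_current / (KB_KJMOL * (params$bias_factor - 1) *
                        params$temperature))
}

## hills data frame: columns time, center_1..d, sigma_1..d, height, biasf
.hills_dim <- function(hills) {
  d <- sum(grepl("^center_", names(hills)))
  if (d == 0L) stop("not a hills table (no center_* columns)")
  d
}

.hills_centers <- function(hills, d = .hills_dim(hills))
  as.matrix(hills[paste0("center_", seq_len(d))])

.hills_sigmas <- function(hills, d = .hills_dim(hills))
  as.matrix(hills[paste0("sigma_", seq_len(d))])

#' Metadynamics bias potential from a hill list
#'
#' `V(x) = sum_k height_k * exp(-sum_d (x_d - center_kd)^2 / (2 sigma_kd^2))`
#' evaluated by direct summation over all hills (no truncation).
#'
#' @param hills hills data frame (see [read_hills()]); may have zero rows.
#' @param x numeric vector (one CV point) or matrix of points in rows.
#' @return Bias energies, kJ/mol (numeric vector, one per point).
#' @export
bias_value <- function(hills, x) {
  if (nrow(hills) == 0L)
    return(numeric(if (is.null(dim(x))) 1L else nrow(x)))
  d <- .hills_dim(hills)
  x <- .as_points(x, d)
  ctr <- .hills_centers(hills, d)
  sig <- .hills_sigmas(hills, d)
  h <- hills$height
  vapply(seq_len(nrow(x)), function(i) {
    z <- sweep(ctr, 2L, x[i, ], "-") / sig
    sum(h * exp(-0.5 * rowSums(z^2)))
  }, numeric(1L))
}

#' Gradient of the metadynamics bias
#'
#' Analytic derivative of [bias_value()] with respect to the CV point.
#'
#' @inheritParams bias_value
#' @return Matrix of gradients (kJ/mol per CV unit), one row per point.
#' @export
bias_gradient <- function(hills, x) {
  d <- .hills_dim(if (nrow(hills) > 0L) hills else
    stop("empty hill list has an all-zero gradient; pass >= 1 hill"))
  x <- .as_points(x, d)
  ctr <- .hills_centers(hills, d)
  sig <- .hills_sigmas(hills, d)
  h <- hills$height
  t(vapply(seq_len(nrow(x)), function(i) {
    z <- sweep(ctr, 2L, x[i, ], "-") / sig
    g <- h * exp(-0.5 * rowSums(z^2))
    colSums(g * z / sig)   # d/dx exp(-(x-c)^2/2s^2) = (c-x)/s^2 * exp(...)
  }, numeric(d)))
}

#' Run metadynamics with Langevin dynamics on a toy potential
#'
#' Samples the potential (plus accumulated bias) with the BAOAB
#' discretization of Langevin dynamics, depositing one Gaussian hill at the
#' current CV point every `params$pace` ps.  The potential gradient and the
#' bias are tabulated on a fine grid and linearly interpolated; reflecting
#' walls act at the domain boundary.  With a fixed seed the whole run
#' (trajectory and hills) is bit-reproducible.
#'
#' @param potential a [toy_potential()] (1 or 2 CVs).
#' @param params a [meta_params()]; set `height = 0` for unbiased dynamics.
#' @param dt integration time step, ps (the pace must be an integer
#'   multiple of `dt`).
#' @param friction Langevin friction, 1/ps.
#' @param temperature K.
#' @param n_steps number of integration steps.
#' @param seed integer RNG seed.
#' @param x0 starting CV point (default: domain midpoint).
#' @param mass fictitious particle mass per CV (length 1 or one per CV).
#'   Unequal CV stiffnesses need unequal masses so that both CVs relax
#'   faster than the deposition pace (quasi-static filling).
#' @param grid_n nodes per CV axis for the tabulated gradient/bias grids.
#' @param record_stride record the CV point every this many steps
#'   (default: the deposition pace, mirroring a 0.5 ps saving stride).
#' @return List of class `metadyn_run` with `colvar` (data frame: time,
#'   cv_1\[, cv_2\]), `hills` (hills data frame), `bias_grid`, `x_final`
#'   and the run parameters.
#' @export
run_metadynamics <- function(potential, params, dt = 0.002, friction = 1,
                             temperature = 300, n_steps = 1000L,
                             seed = 1L, x0 = NULL, mass = 1,
                             grid_n = NULL, record_stride = NULL) {
  stopifnot(inherits(potential, "toy_potential"),
            inherits(params, "meta_params"))
  if (dt <= 0) stop("'dt' must be > 0")
  d <- nrow(potential$domain)
  pace_steps <- round(params$pace / dt)
  if (pace_steps < 1L || abs(pace_steps * dt - params$pace) > 1e-9)
    stop("'pace' must be a positive integer multiple of 'dt'")
  if (length(params$widths) == 1L && d > 1L)
    params$widths <- rep(params$widths, d)
  if (length(params$widths) != d)
    stop("'widths' must have one entry per CV")
  if (is.null(grid_n)) grid_n <- if (d == 1L) 4001L else c(451L, 451L)
  if (length(grid_n) == 1L) grid_n <- rep(grid_n, d)
  if (is.null(record_stride)) record_stride <- pace_steps
  if (is.null(x0)) x0 <- rowMeans(potential$domain)
  if (length(x0) != d) stop("'x0' must have one entry per CV")
  if (length(mass) == 1L) mass <- rep(mass, d)
  if (length(mass) != d || any(mass <= 0))
    stop("'mass' must be positive, length 1 or one per CV")
  if (any(x0 < potential$domain[, 1L]) || any(x0 > potential$domain[, 2L]))
    stop("'x0' outside the potential domain")

  axes <- lapply(seq_len(d), function(k)
    seq(potential$domain[k, 1L], potential$domain[k, 2L],
        length.out = grid_n[k]))
  nodes <- if (d == 1L) matrix(axes[[1L]], ncol = 1L) else
    as.matrix(expand.grid(axes[[1L]], axes[[2L]], KEEP.OUT.ATTRS = FALSE))
  ugrad <- potential$gradient(nodes)
  if (is.null(dim(ugrad))) ugrad <- matrix(ugrad, ncol = 1L)
  if (!all(is.finite(ugrad)))
    stop("potential gradient is not finite everywhere on the grid")

  set.seed(seed)
  res <- .metadyn_core(potential$domain[, 1L], potential$domain[, 2L],
                       as.integer(grid_n), ugrad, as.numeric(x0),
                       as.numeric(mass), dt, friction, temperature,
                       as.integer(n_steps), as.integer(pace_steps),
                       as.integer(record_stride),
                       params$height, params$widths,
                       params$mode == "well_tempered", params$bias_factor,
                       hill_cutoff_sigmas = 8)
  hills <- as.data.frame(res$hills)
  names(hills) <- c("time", paste0("center_", seq_len(d)),
                    paste0("sigma_", seq_len(d)), "height", "biasf")
  colvar <- as.data.frame(res$colvar)
  names(colvar) <- c("time", paste0("cv_", seq_len(d)))
  structure(list(colvar = colvar, hills = hills,
                 bias_grid = res$bias_grid, axes = axes,
                 x_final = res$x_final, params = params, dt = dt,
                 friction = friction, temperature = temperature,
                 seed = seed, potential = potential$name),
            class = "metadyn_run")
}

#' @export
print.metadyn_run <- function(x, ...) {
  cat("<metadyn_run>", x$potential, "\n")
  cat(sprintf("  %d hills (%s mode), %d recorded frames, T = %g K\n",
              nrow(x$hills), x$params$mode, nrow(x$colvar), x$temperature))
  invisible(x)
}

#' Write a HILLS file
#'
#' PLUMED-style whitespace-delimited text: one hill per line with columns
#' time, per-CV center, per-CV sigma, height and bias factor (1.0 in
#' standard mode), under a `#! FIELDS` header.
#'
#' @param hills hills data frame.
#' @param path output file.
#' @export
write_hills <- function(hills, path) {
  d <- .hills_dim(hills)
  cols <- c("time", paste0("center_", seq_len(d)),
            paste0("sigma_", seq_len(d)), "height", "biasf")
  if (!"biasf" %in% names(hills)) hills$biasf <- 1.0
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(cols, collapse = " ")), con)
  write.table(format(hills[cols], digits = 12, scientific = FALSE,
                     trim = TRUE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a HILLS file
#'
#' @param path file written by [write_hills()] (or PLUMED).
#' @return Hills data frame (time, center_*, sigma_*, height, biasf).
#' @export
read_hills <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty HILLS file: ", path)
  header <- lines[[1L]]
  if (!grepl("^#!\\s*FIELDS", header))
    stop("not a HILLS file (missing '#! FIELDS' header): ", path)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", header), "\\s+")[[1L]]
  body <- lines[-1L]
  body <- body[!grepl("^\\s*(#|$)", body)]
  if (length(body) == 0L) {
    out <- as.data.frame(matrix(numeric(0), ncol = length(fields)))
    names(out) <- fields
    return(out)
  }
  parsed <- strsplit(trimws(body), "\\s+")
  nf <- lengths(parsed)
  if (any(nf != length(fields))) {
    bad <- which(nf != length(fields))[1L]
    stop(sprintf("malformed HILLS line %d in %s: expected %d fields, got %d",
                 bad + 1L, path, length(fields), nf[bad]))
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(parsed)), ncol = length(fields), byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(rowSums(is.na(vals)) > 0)[1L]
    stop(sprintf("malformed HILLS line %d in %s: non-numeric field",
                 bad + 1L, path))
  }
  out <- as.data.frame(vals)
  names(out) <- fields
  if ("time" %in% names(out) && is.unsorted(out$time))
    warning("non-monotonic times in HILLS file: ", path)
  out
}
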