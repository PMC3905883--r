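## Collective variables describing inhibitor unbinding: center-of-mass
## distance and coordination number, plus the data-driven parametrization of
## the coordination switching function from the radial atom-pair
## distribution.

#' Switching-function parameters for the coordination number
#'
#' The pairwise contact weight is the rational switching function
#' `s(r) = (1 - x^n) / (1 - x^m)` with `x = (r - d0) / r0`; pairs closer
#' than `d0` contribute the limiting value 1 (the r -> d0 limit).
#'
#' @param d0 offset, nm (>= 0); typically the first peak of the radial
#'   atom-pair distribution.
#' @param r0 scale, nm (> 0); typically the full width at half maximum of
#'   the same distribution.
#' @param n_exp,m_exp even positive integer exponents with `m_exp > n_exp`.
#' @return An object of class `switching_params`.
#' @export
switching_params <- function(d0 = 0.35, r0 = 0.1, n_exp = 6L, m_exp = 12L) {
  if (!is.numeric(r0) || r0 <= 0) stop("'r0' must be > 0")
  if (d0 < 0) stop("'d0' must be >= 0")
  n_exp <- as.integer(n_exp); m_exp <- as.integer(m_exp)
  if (n_exp <= 0L || m_exp <= n_exp)
    stop("exponents must satisfy m_exp > n_exp > 0")
  if (n_exp %% 2L != 0L || m_exp %% 2L != 0L)
    stop("exponents must be even")
  structure(list(d0 = d0, r0 = r0, n_exp = n_exp, m_exp = m_exp),
            class = "switching_params")
}

#' Rational switching function
#'
#' @param r distances, nm (vectorised).
#' @param p a [switching_params()].
#' @return Contact weights in (0, 1].
#' @export
switching_function <- function(r, p) {
  stopifnot(inherits(p, "switching_params"))
  x <- (r - p$d0) / p$r0
  x[x < 0] <- 0                       # r < d0: limiting value s = 1
  n <- p$n_exp; m <- p$m_exp
  s <- numeric(length(x))
  near1 <- abs(x - 1) < 1e-6
  ## removable singularity at x = 1: s -> n/m; first-order expansion
  s[near1] <- (n / m) * (1 + (n - m) / 2 * (x[near1] - 1))
  xr <- x[!near1]
  s[!near1] <- (1 - xr^n) / (1 - xr^m)
  s
}

.check_group <- function(idx, n_atoms, what = "group") {
  idx <- as.integer(idx)
  if (length(idx) == 0L) stop("empty ", what)
  if (any(idx < 1L) || any(idx > n_atoms))
    stop(what, " contains atom indices outside the topology")
  idx
}

#' Center of mass of an atom group
#'
#' @param frame numeric matrix n_atoms x 3, nm.
#' @param idx atom indices of the group.
#' @param masses per-atom masses, amu (length n_atoms).
#' @return Numeric length-3 mass-weighted centroid.
#' @export
center_of_mass <- function(frame, idx, masses) {
  idx <- .check_group(idx, nrow(frame))
  if (length(masses) != nrow(frame))
    stop("'masses' length must match the number of atoms in the frame")
  if (any(masses[idx] <= 0)) stop("masses must be > 0")
  w <- masses[idx] / sum(masses[idx])
  colSums(frame[idx, , drop = FALSE] * w)
}

#' Distance between the centers of mass of two atom groups
#'
#' @inheritParams center_of_mass
#' @param a,b atom index vectors of the two groups.
#' @return Distance in nm (>= 0); symmetric in the two groups.
#' @export
com_distance <- function(frame, a, b, masses) {
  ca <- center_of_mass(frame, a, masses)
  cb <- center_of_mass(frame, b, masses)
  sqrt(sum((ca - cb)^2))
}

#' Coordination number between two atom groups
#'
#' Sum over all inter-group atom pairs of the rational switching function of
#' the pair distance: a smooth, differentiable count of contacts.
#'
#' @inheritParams com_distance
#' @param p a [switching_params()].
#' @return Dimensionless contact count.
#' @export
coordination_number <- function(frame, a, b, p) {
  a <- .check_group(a, nrow(frame), "group a")
  b <- .check_group(b, nrow(frame), "group b")
  ra <- frame[a, , drop = FALSE]
  rb <- frame[b, , drop = FALSE]
  d2 <- outer(rowSums(ra^2), rowSums(rb^2), "+") - 2 * tcrossprod(ra, rb)
  d2[d2 < 0] <- 0
  sum(switching_function(sqrt(d2), p))
}

#' Radial atom-pair distance distribution
#'
#' Histogram of all inter-group atom-pair distances pooled over the frames
#' of a trajectory; the empirical radial distribution used to parametrize
#' the coordination switching function.
#'
#' @param traj list of coordinate matrices (n_atoms x 3, nm) or a single
#'   matrix for one frame.
#' @param a,b atom index vectors of the two groups.
#' @param bin_width histogram bin width, nm (> 0).
#' @return A list of class `pair_histogram` with `counts`, `breaks` and
#'   `mids` (bin centers, nm).
#' @export
pair_distance_distribution <- function(traj, a, b, bin_width = 0.005) {
  if (is.matrix(traj)) traj <- list(traj)
  if (length(traj) == 0L) stop("empty trajectory")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("'bin_width' must be > 0")
  n_atoms <- nrow(traj[[1L]])
  a <- .check_group(a, n_atoms, "group a")
  b <- .check_group(b, n_atoms, "group b")
  dists <- unlist(lapply(traj, function(fr) {
    ra <- fr[a, , drop = FALSE]
    rb <- fr[b, , drop = FALSE]
    d2 <- outer(rowSums(ra^2), rowSums(rb^2), "+") - 2 * tcrossprod(ra, rb)
    d2[d2 < 0] <- 0
    sqrt(d2)
  }), use.names = FALSE)
  breaks <- seq(0, (floor(max(dists) / bin_width) + 1L) * bin_width,
                by = bin_width)
  counts <- tabulate(findInterval(dists, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1L)
  structure(list(counts = counts, breaks = breaks,
                 mids = (breaks[-1L] + breaks[-length(breaks)]) / 2),
            class = "pair_histogram")
}

#' Fit switching-function parameters from a pair-distance histogram
#'
#' `d0` is set to the center of the first local maximum of the histogram
#' (scanning from zero; bins below 5% of the global maximum are ignored as
#' sampling noise) and `r0` to the full width at half maximum of the
#' contiguous region around that peak.  Exponents are the package defaults
#' (n = 6, m = 12).
#'
#' @param hist a `pair_histogram` from [pair_distance_distribution()].
#' @param noise_frac bins with counts below this fraction of the global
#'   maximum are not eligible as peaks (default 0.05).
#' @return A [switching_params()].
#' @export
fit_switching_params <- function(hist, noise_frac = 0.05) {
  stopifnot(inherits(hist, "pair_histogram"))
  cts <- hist$counts
  if (length(cts) == 0L || all(cts == 0)) stop("empty histogram")
  if (length(unique(cts)) == 1L) stop("flat histogram has no peak")
  floor_ct <- noise_frac * max(cts)
  nb <- length(cts)
  peak <- NA_integer_
  for (i in seq_len(nb)) {
    if (cts[i] < floor_ct) next
    left <- if (i > 1L) cts[i - 1L] else -Inf
    right <- if (i < nb) cts[i + 1L] else -Inf
    if (cts[i] >= left && cts[i] >= right) { peak <- i; break }
  }
  if (is.na(peak)) stop("histogram has no local maximum above noise floor")
  half <- cts[peak] / 2
  lo <- peak
  while (lo > 1L && cts[lo - 1L] >= half) lo <- lo - 1L
  hi <- peak
  while (hi < nb && cts[hi + 1L] >= half) hi <- hi + 1L
  bw <- hist$breaks[2L] - hist$breaks[1L]
  switching_params(d0 = hist$mids[peak], r0 = (hi - lo + 1L) * bw)
}

#' Write a COLVAR-style CV time series
#'
#' Whitespace-delimited text with a PLUMED-style `#! FIELDS` header.
#'
#' @param colvar data frame with column `time` (ps) and one column per CV.
#' @param path output file.
#' @export
write_colvar <- function(colvar, path) {
  stopifnot(is.data.frame(colvar), "time" %in% names(colvar))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(colvar), collapse = " ")), con)
  write.table(format(colvar, digits = 10, scientific = FALSE, trim = TRUE),
              con, quote = FALSE, row.names = FALSE, col.names = FALSE)
}

#' Read a COLVAR-style CV time series
#'
#' @param path file written by [write_colvar()] (or PLUMED).
#' @return Data frame with the columns named in the header.
#' @export
read_colvar <- function(path) {
  header <- readLines(path, n = 1L)
  if (!grepl("^#!\\s*FIELDS", header))
    stop("not a COLVAR file (missing '#! FIELDS' header): ", path)
  fields <- strsplit(sub("^#!\\s*FIELDS\\s+", "", header), "\\s+")[[1L]]
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = fields)
  df
}
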