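## Analytic toy potentials used as stand-ins for the all-atom unbinding
## free-energy landscape.  All energies in kJ/mol, distances in nm, the
## contact-like coordinate is dimensionless (a coordination-number count).

#' Construct a toy potential
#'
#' A `toy_potential` bundles a vectorised energy function, its analytic
#' gradient and a rectangular domain.  Energy and gradient accept a numeric
#' vector (one point) or a matrix with one point per row.
#'
#' @param name identifier.
#' @param energy function(matrix n x d) -> numeric n, in kJ/mol.
#' @param gradient function(matrix n x d) -> matrix n x d, kJ/mol per CV unit.
#' @param domain matrix d x 2 of per-CV (min, max).
#' @return An object of class `toy_potential`.
#' @export
toy_potential <- function(name, energy, gradient, domain) {
  domain <- matrix(as.numeric(domain), ncol = 2L)
  stopifnot(is.function(energy), is.function(gradient),
            all(domain[, 2L] > domain[, 1L]))
  structure(list(name = name, energy = energy, gradient = gradient,
                 domain = domain),
            class = "toy_potential")
}

#' @export
print.toy_potential <- function(x, ...) {
  cat("<toy_potential>", x$name, "\n")
  for (i in seq_len(nrow(x$domain)))
    cat(sprintf("  CV%d domain: [%g, %g]\n", i, x$domain[i, 1], x$domain[i, 2]))
  invisible(x)
}

## Coerce a point / matrix of points to an n x d matrix.
.as_points <- function(x, d) {
  if (is.null(dim(x))) x <- matrix(x, ncol = d, byrow = FALSE)
  stopifnot(ncol(x) == d)
  x
}

#' Evaluate a toy potential
#'
#' @param pot a [toy_potential()].
#' @param x numeric vector (one point) or matrix of points in rows.
#' @return Energies in kJ/mol (numeric vector).
#' @export
potential_energy <- function(pot, x) {
  pot$energy(.as_points(x, nrow(pot$domain)))
}

#' Evaluate the analytic gradient of a toy potential
#'
#' @inheritParams potential_energy
#' @return Matrix of gradients (kJ/mol per CV unit), one row per point.
#' @export
potential_gradient <- function(pot, x) {
  pot$gradient(.as_points(x, nrow(pot$domain)))
}

#' Symmetric double-well potential
#'
#' Quartic double well `V(x) = barrier * ((x/a)^2 - 1)^2` with `a =
#' well_separation / 2`: two equal-energy minima at `x = -a, +a` (V = 0) and
#' a barrier of exactly `barrier` kJ/mol at `x = 0`.  The standard 1-D
#' validation system for the metadynamics engine.
#'
#' @param barrier inter-well barrier height, kJ/mol (> 0).
#' @param well_separation distance between the two minima, CV units (> 0).
#' @return A [toy_potential()] with domain `[-well_separation,
#'   well_separation]`.
#' @export
make_double_well <- function(barrier = 20, well_separation = 2) {
  if (!is.numeric(barrier) || length(barrier) != 1L || barrier <= 0)
    stop("'barrier' must be a single positive number")
  if (!is.numeric(well_separation) || length(well_separation) != 1L ||
      well_separation <= 0)
    stop("'well_separation' must be a single positive number")
  a <- well_separation / 2
  energy <- function(x) {
    u <- (x[, 1L] / a)^2 - 1
    barrier * u^2
  }
  gradient <- function(x) {
    u <- (x[, 1L] / a)^2 - 1
    matrix(barrier * 4 * u * x[, 1L] / a^2, ncol = 1L)
  }
  toy_potential(sprintf("double_well(barrier=%g, sep=%g)", barrier,
                        well_separation),
                energy, gradient,
                domain = c(-well_separation, well_separation))
}

#' Harmonic well
#'
#' `V(x) = 0.5 * k * |x - center|^2`; used for equipartition checks of the
#' Langevin integrator.
#'
#' @param k force constant, kJ/mol per CV unit squared (> 0).
#' @param center well center (numeric vector, one entry per CV).
#' @param halfwidth domain half-width around the center.
#' @return A [toy_potential()].
#' @export
make_harmonic_well <- function(k = 100, center = 0, halfwidth = 2) {
  stopifnot(k > 0, halfwidth > 0)
  d <- length(center)
  energy <- function(x) {
    dx <- sweep(x, 2L, center)
    0.5 * k * rowSums(dx^2)
  }
  gradient <- function(x) k * sweep(x, 2L, center)
  toy_potential(sprintf("harmonic(k=%g)", k), energy, gradient,
                domain = cbind(center - halfwidth, center + halfwidth))
}

## C2 quintic smoothstep: 0 below the ramp, 1 above, 6u^5-15u^4+10u^3 inside.
.sstep <- function(d, from, to) {
  u <- (d - from) / (to - from)
  u <- pmin(pmax(u, 0), 1)
  u * u * u * (u * (u * 6 - 15) + 10)
}

.sstep_deriv <- function(d, from, to) {
  u <- (d - from) / (to - from)
  inside <- u > 0 & u < 1
  out <- numeric(length(d))
  ui <- u[inside]
  out[inside] <- 30 * ui * ui * (1 - ui)^2 / (to - from)
  out
}

## Piecewise-smoothstep profile through (knot, value) pairs with zero slope
## at every knot; exactly constant outside the knot range.
.profile_eval <- function(d, knots, values) {
  out <- rep(values[1L], length(d))
  for (i in seq_len(length(knots) - 1L)) {
    s <- .sstep(d, knots[i], knots[i + 1L])
    out <- out + (values[i + 1L] - values[i]) * s
  }
  out
}

.profile_deriv <- function(d, knots, values) {
  out <- numeric(length(d))
  for (i in seq_len(length(knots) - 1L)) {
    out <- out + (values[i + 1L] - values[i]) *
      .sstep_deriv(d, knots[i], knots[i + 1L])
  }
  out
}

#' Synthetic two-CV unbinding landscape
#'
#' Builds a 2-D toy free-energy landscape over a distance-like CV
#' (`d`, nm, domain \[0, 4.5\]) and a contact-like CV (`c`, dimensionless,
#' domain \[0, 400\]) with the topology of a drug-unbinding surface: a deep
#' bound basin B at small distance / high contacts, a transition state Ts, a
#' shallower intermediate basin I at ~1.6 nm / low contacts, an exit barrier
#' Ts_out and an open, exactly flat exit channel.  The landscape is
#' `V(d, c) = f(d) + 0.5 * k_c * (c - c0(d))^2` where `f` is a piecewise
#' cubic-smoothstep profile along the unbinding valley `c0(d)`; the valley
#' transitions are placed strictly inside sloped segments of `f` so that the
#' grid landscape has exactly two strict local minima.
#'
#' Energy levels (B minimum at 0): Ts at `barrier_BTs`; I at
#' `barrier_BTs - depths["I"]` (`depths["I"]` is the intermediate's depth
#' below the B/I transition state); Ts_out at `depths["B"] - depths["I"]`;
#' beyond Ts_out the exit channel slopes down to a flat tail at
#' `0.1 * barrier_BTs`.  The minimax saddle between B and I therefore sits
#' exactly `barrier_BTs` above B.
#'
#' @param depths named numeric `c(B = , I = )`, kJ/mol, both > 0.  Defaults
#'   scale with the barrier (`B = 1.5 * barrier_BTs`, `I = 0.75 *
#'   barrier_BTs`) so that barrier sweeps rescale the landscape
#'   self-similarly.
#' @param barrier_BTs activation energy of the B -> Ts step, kJ/mol (> 0).
#' @return A [toy_potential()] with `minima`, `saddle` and `kc` attached as
#'   fields (exact CV coordinates and energies of B, I and the Ts).
#' @export
make_unbinding_landscape <- function(depths = NULL, barrier_BTs = 20) {
  if (!is.numeric(barrier_BTs) || length(barrier_BTs) != 1L ||
      barrier_BTs <= 0)
    stop("'barrier_BTs' must be a single positive number")
  if (is.null(depths))
    depths <- c(B = 1.5 * barrier_BTs, I = 0.75 * barrier_BTs)
  if (!all(c("B", "I") %in% names(depths)) || any(depths[c("B", "I")] <= 0))
    stop("'depths' must be a named vector with positive entries B and I")
  b <- barrier_BTs
  dB <- unname(depths["B"])
  dI <- unname(depths["I"])
  ## Level scheme; reject geometries in which a basin or barrier degenerates.
  f_B <- 0
  f_Ts <- b
  f_I <- b - dI
  f_out <- dB - dI          # Ts_out level
  if (dB <= b)
    stop("degenerate geometry: depths['B'] must exceed barrier_BTs ",
         "(otherwise the exit barrier drops below the intermediate)")
  if (dB >= b + dI)
    stop("degenerate geometry: depths['B'] must be below barrier_BTs + ",
         "depths['I'] (otherwise Ts_out overlaps the main barrier)")
  if (dI >= b)
    stop("degenerate geometry: depths['I'] must be below barrier_BTs ",
         "(otherwise the intermediate sinks below the bound state)")
  ## exit channel: a genuine downhill slope (drift-driven transit) ending
  ## just above the bound-state level, exactly flat over the last 0.2 nm
  f_exit <- 0.1 * b

  ## f(d): valley profile.  Zero slope at every knot; constant after 4.3 nm.
  fknots  <- c(0.0, 0.3, 1.0, 1.6, 2.1, 4.3)
  fvalues <- c(f_Ts, f_B, f_Ts, f_I, f_out, f_exit)
  ## c0(d): valley center in the contact CV.  All transitions sit strictly
  ## inside sloped segments of f and end before the flat exit plateau.
  cknots  <- c(0.45, 0.85, 1.12, 1.48, 1.72, 1.98)
  cvalues <- c(300, 150, 150, 20, 20, 0)
  kc <- 0.002  # transverse stiffness, kJ/mol per contact^2

  c0_eval <- function(d) {
    out <- rep(300, length(d))
    for (i in c(1L, 3L, 5L)) {
      s <- .sstep(d, cknots[i], cknots[i + 1L])
      out <- out + (cvalues[i + 1L] - cvalues[i]) * s
    }
    out
  }
  c0_deriv <- function(d) {
    out <- numeric(length(d))
    for (i in c(1L, 3L, 5L)) {
      out <- out + (cvalues[i + 1L] - cvalues[i]) *
        .sstep_deriv(d, cknots[i], cknots[i + 1L])
    }
    out
  }

  energy <- function(x) {
    d <- x[, 1L]; cc <- x[, 2L]
    .profile_eval(d, fknots, fvalues) + 0.5 * kc * (cc - c0_eval(d))^2
  }
  gradient <- function(x) {
    d <- x[, 1L]; cc <- x[, 2L]
    dev <- cc - c0_eval(d)
    gd <- .profile_deriv(d, fknots, fvalues) - kc * dev * c0_deriv(d)
    gc <- kc * dev
    cbind(gd, gc, deparse.level = 0)
  }

  pot <- toy_potential(
    sprintf("unbinding(B=%g, I=%g, barrier=%g)", dB, dI, b),
    energy, gradient,
    domain = rbind(c(0, 4.5), c(0, 400)))
  pot$minima <- list(
    B = list(cv = c(0.3, c0_eval(0.3)), energy = f_B),
    I = list(cv = c(1.6, c0_eval(1.6)), energy = f_I))
  pot$saddle <- list(cv = c(1.0, c0_eval(1.0)), energy = f_Ts)
  pot$kc <- kc
  pot
}
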