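## Mock ternary-complex specification and trajectory generator: small
## pseudo-atom systems with prescribed per-state hydrogen-bond occupancies,
## per-atom fluctuation amplitudes and a frame -> state sequence, standing
## in for the protein-DNA-drug trajectories the structural operators were
## designed for.

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06)

#' Atomic mass from element symbol
#'
#' @param element character vector of element symbols.
#' @return Masses in amu.
#' @export
element_mass <- function(element) {
  m <- .ELEMENT_MASS[element]
  if (anyNA(m)) stop("unknown element(s): ",
                     paste(unique(element[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Build a mock-complex topology table
#'
#' @param atoms data frame with columns `name`, `element`, `group` (one of
#'   `ligand`, `base`, `residue`), `base_position` (-2, -1, +1, +2 or NA),
#'   `strand` (`intact`, `scissile` or NA), `residue_name`, `residue_id`,
#'   `is_donor`, `is_acceptor`, `donor_hydrogen` (serial of the bound
#'   hydrogen, NA otherwise) and mean coordinates `x`, `y`, `z` (nm).
#'   Masses are inferred from the element.
#' @return The validated topology (class `complex_topology`).
#' @export
complex_topology <- function(atoms) {
  req <- c("name", "element", "group", "base_position", "strand",
           "residue_name", "residue_id", "is_donor", "is_acceptor",
           "donor_hydrogen", "x", "y", "z")
  miss <- setdiff(req, names(atoms))
  if (length(miss) > 0L)
    stop("topology lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty atom list")
  atoms$serial <- seq_len(nrow(atoms))
  atoms$mass <- element_mass(atoms$element)
  bad <- !atoms$group %in% c("ligand", "base", "residue")
  if (any(bad)) stop("unknown group label(s): ",
                     paste(unique(atoms$group[bad]), collapse = ", "))
  hd <- atoms$donor_hydrogen[atoms$is_donor]
  if (any(!is.na(hd) & (hd < 1L | hd > nrow(atoms))))
    stop("donor_hydrogen serial out of range")
  class(atoms) <- c("complex_topology", "data.frame")
  atoms
}

#' Mock ternary-complex specification
#'
#' Declares the statistical structure the generated trajectory must have:
#' which states exist, the per-state probability that each donor/acceptor
#' pair is in hydrogen-bond geometry, the per-atom isotropic fluctuation
#' sigma and the frame -> state sequence.
#'
#' @param topology a [complex_topology()].
#' @param states character vector of state labels.
#' @param occupancy data frame `donor`, `acceptor` (atom serials), `state`,
#'   `p` (probability in \[0, 1\]); pairs absent for a state have p = 0.
#' @param sigma per-atom fluctuation sigma, nm (length 1 or n_atoms, >= 0).
#' @param state_sequence character vector, one state label per frame
#'   (recycled to the requested frame count).
#' @param seed integer seed making the generated trajectory deterministic.
#' @return An object of class `mock_complex_spec`.
#' @export
mock_complex_spec <- function(topology, states, occupancy, sigma,
                              state_sequence, seed = 42L) {
  stopifnot(inherits(topology, "complex_topology"))
  if (length(states) == 0L) stop("need at least one state")
  if (any(occupancy$p < 0 | occupancy$p > 1))
    stop("occupancies must lie in [0, 1]")
  if (!all(occupancy$state %in% states))
    stop("occupancy table names unknown state(s)")
  if (!all(state_sequence %in% states))
    stop("state sequence contains unknown state label(s): ",
         paste(setdiff(unique(state_sequence), states), collapse = ", "))
  if (length(sigma) == 1L) sigma <- rep(sigma, nrow(topology))
  if (length(sigma) != nrow(topology))
    stop("'sigma' must have length 1 or n_atoms")
  if (any(sigma < 0)) stop("sigmas must be >= 0")
  ok_d <- topology$is_donor[occupancy$donor]
  ok_a <- topology$is_acceptor[occupancy$acceptor]
  if (any(!ok_d) || any(!ok_a))
    stop("occupancy pairs must link donor atoms to acceptor atoms")
  if (anyDuplicated(occupancy$acceptor[!duplicated(
        occupancy[c("donor", "acceptor")])]) &&
      any(table(unique(occupancy[c("donor", "acceptor")])$acceptor) > 1L))
    warning("an acceptor is shared between donors; ",
            "generated geometries follow the first pair listed")
  structure(list(topology = topology, states = states,
                 occupancy = occupancy, sigma = sigma,
                 state_sequence = as.character(state_sequence),
                 seed = as.integer(seed)),
            class = "mock_complex_spec")
}

## H-bond geometry used by the generator: donor-acceptor distance when the
## bond is present / absent, and the donor-hydrogen bond length (all nm).
.HB_PRESENT_NM <- 0.30
.HB_ABSENT_NM <- 0.60
.DH_BOND_NM <- 0.10

#' Generate a mock trajectory with prescribed statistics
#'
#' Per frame, each declared hydrogen-bond pair is put into hydrogen-bond
#' geometry (donor-acceptor 0.30 nm, colinear D-H-A) with exactly its
#' state's occupancy probability, and broken geometry (0.60 nm) otherwise;
#' every atom then jitters isotropically around its mean with its Gaussian
#' sigma.  The draw is seeded from the spec, so a fixed spec yields a
#' bitwise-identical trajectory; the caller's RNG state is untouched.
#'
#' @param spec a [mock_complex_spec()].
#' @param n_frames number of frames (>= 1; default: the length of the
#'   spec's state sequence).
#' @param dt_ps time between saved frames, ps (default 0.5).
#' @return List of class `mock_trajectory`: `frames` (list of n_atoms x 3
#'   matrices, nm), `times` (ps), `states` (per-frame labels) and
#'   `topology`.
#' @export
generate_mock_trajectory <- function(spec, n_frames = NULL, dt_ps = 0.5) {
  stopifnot(inherits(spec, "mock_complex_spec"))
  if (is.null(n_frames)) n_frames <- length(spec$state_sequence)
  n_frames <- as.integer(n_frames)
  if (n_frames < 1L) stop("'n_frames' must be >= 1")
  states <- rep_len(spec$state_sequence, n_frames)
  topo <- spec$topology
  n_atoms <- nrow(topo)
  base_xyz <- as.matrix(topo[, c("x", "y", "z")])

  ## deterministic draw without disturbing the caller's RNG
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  occ <- spec$occupancy
  pairs <- unique(occ[c("donor", "acceptor")])
  ## per-pair per-state probability lookup (0 when unspecified)
  pmat <- matrix(0, nrow(pairs), length(spec$states),
                 dimnames = list(NULL, spec$states))
  for (r in seq_len(nrow(occ))) {
    k <- which(pairs$donor == occ$donor[r] &
                 pairs$acceptor == occ$acceptor[r])
    pmat[k, occ$state[r]] <- occ$p[r]
  }
  ## Bernoulli presence per pair and frame
  present <- matrix(FALSE, n_frames, nrow(pairs))
  for (k in seq_len(nrow(pairs)))
    present[, k] <- runif(n_frames) < pmat[k, states]

  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- base_xyz
    for (k in seq_len(nrow(pairs))) {
      d <- pairs$donor[k]; a <- pairs$acceptor[k]
      u <- base_xyz[a, ] - base_xyz[d, ]
      u <- u / sqrt(sum(u^2))
      r_da <- if (present[f, k]) .HB_PRESENT_NM else .HB_ABSENT_NM
      xyz[a, ] <- base_xyz[d, ] + r_da * u
      h <- topo$donor_hydrogen[d]
      if (!is.na(h)) xyz[h, ] <- base_xyz[d, ] + .DH_BOND_NM * u
    }
    xyz <- xyz + matrix(rnorm(3L * n_atoms, sd = spec$sigma),
                        n_atoms, 3L)
    frames[[f]] <- xyz
  }
  structure(list(frames = frames, times = seq_len(n_frames) * dt_ps,
                 states = states, topology = topo),
            class = "mock_trajectory")
}

#' @export
print.mock_trajectory <- function(x, ...) {
  cat("<mock_trajectory>", length(x$frames), "frames,",
      nrow(x$topology), "atoms\n")
  print(table(x$states))
  invisible(x)
}

#' Default mock ternary complex
#'
#' A ~60 pseudo-atom stand-in for a protein-DNA-drug ternary complex: a
#' 6-atom ligand between the base groups at positions -1 and +1, bases at
#' positions -2..+2 on both strands, and four protein-like residues
#' carrying donors near the ligand and the cleavage site.  The default
#' occupancy table mirrors the qualitative pattern of a bound / transition
#' / intermediate state analysis, including a 0.49-occupancy
#' residue-to-ligand bond in the bound state.
#'
#' @param states state labels (default B, Ts, I).
#' @param seed integer seed.
#' @param frames_per_state named integer vector of frames per state used to
#'   build the default state sequence (defaults mirror a bound-state-heavy
#'   sampling: B 7512, Ts 22, I 631).
#' @return A [mock_complex_spec()].
#' @export
default_mock_spec <- function(states = c("B", "Ts", "I"), seed = 42L,
                              frames_per_state = c(B = 7512L, Ts = 22L,
                                                   I = 631L)) {
  atoms <- list()
  add <- function(name, element, group, pos, strand, rname, rid,
                  x, y, z, donor = FALSE, acceptor = FALSE, hyd = NA_integer_)
    data.frame(name = name, element = element, group = group,
               base_position = pos, strand = strand, residue_name = rname,
               residue_id = rid, is_donor = donor, is_acceptor = acceptor,
               donor_hydrogen = hyd, x = x, y = y, z = z)

  rows <- list()
  ## ligand: 6 atoms around the origin; O1 is an acceptor, N1/H1 a donor
  lig <- rbind(
    add("C1", "C", "ligand", NA, NA, "LIG", 1L, 0.00, 0.00, 0.00),
    add("C2", "C", "ligand", NA, NA, "LIG", 1L, 0.14, 0.00, 0.00),
    add("C3", "C", "ligand", NA, NA, "LIG", 1L, 0.07, 0.12, 0.00),
    add("O1", "O", "ligand", NA, NA, "LIG", 1L, 0.28, 0.05, 0.05,
        acceptor = TRUE),
    add("N1", "N", "ligand", NA, NA, "LIG", 1L, -0.12, 0.08, 0.02,
        donor = TRUE),
    add("H1", "H", "ligand", NA, NA, "LIG", 1L, -0.20, 0.05, 0.05))
  rows <- c(rows, list(lig))

  ## bases: positions -2..+2 (no 0), both strands, 3 atoms each
  rid <- 2L
  for (pos in c(-2L, -1L, 1L, 2L)) {
    for (strand in c("intact", "scissile")) {
      zoff <- if (strand == "intact") 0.6 else -0.6
      xoff <- pos * 0.35
      nm <- sprintf("%s%+d", ifelse(strand == "intact", "In", "Sc"), pos)
      base <- rbind(
        add("N9", "N", "base", pos, strand, nm, rid,
            xoff, 0.0, zoff, acceptor = TRUE),
        add("C4", "C", "base", pos, strand, nm, rid,
            xoff + 0.13, 0.05, zoff),
        add("O2", "O", "base", pos, strand, nm, rid,
            xoff - 0.05, 0.22, zoff, acceptor = TRUE))
      rows <- c(rows, list(base))
      rid <- rid + 1L
    }
  }

  ## protein-like residues with donor N-H groups near ligand / cleavage site
  res_names <- c("LYS", "ASN", "ARG", "THR")
  res_pos <- rbind(c(-0.45, 0.35, 0.1), c(0.5, 0.4, -0.3),
                   c(-0.6, -0.3, 0.5), c(0.6, -0.35, -0.55))
  for (r in seq_along(res_names)) {
    p <- res_pos[r, ]
    base_serial <- sum(vapply(rows, nrow, integer(1L)))
    res <- rbind(
      add("CA", "C", "residue", NA, NA, res_names[r], rid,
          p[1], p[2], p[3]),
      add("NZ", "N", "residue", NA, NA, res_names[r], rid,
          p[1] + 0.1, p[2] + 0.1, p[3], donor = TRUE,
          hyd = base_serial + 3L),
      add("HZ", "H", "residue", NA, NA, res_names[r], rid,
          p[1] + 0.18, p[2] + 0.15, p[3]),
      add("OG", "O", "residue", NA, NA, res_names[r], rid,
          p[1] - 0.1, p[2] + 0.05, p[3] + 0.1, acceptor = TRUE))
    rows <- c(rows, list(res))
    rid <- rid + 1L
  }
  atoms <- do.call(rbind, rows)
  ## ligand donor N1 -> H1
  atoms$donor_hydrogen[atoms$name == "N1"] <- which(atoms$name == "H1")
  topo <- complex_topology(atoms)

  serial_of <- function(rname, aname)
    topo$serial[topo$residue_name == rname & topo$name == aname]
  ## occupancy pattern: a 0.49 residue->ligand bond in B that vanishes
  ## elsewhere, a Ts-only bond, and a stable residue->base bond
  occupancy <- rbind(
    data.frame(donor = serial_of("LYS", "NZ"),
               acceptor = serial_of("LIG", "O1"),
               state = c("B", "Ts", "I"), p = c(0.49, 0, 0)),
    data.frame(donor = serial_of("ASN", "NZ"),
               acceptor = serial_of("In+1", "O2"),
               state = c("B", "Ts", "I"), p = c(0.0, 0.68, 0.0)),
    data.frame(donor = serial_of("ARG", "NZ"),
               acceptor = serial_of("In-1", "N9"),
               state = c("B", "Ts", "I"), p = c(0.99, 1.0, 0.96)),
    data.frame(donor = serial_of("THR", "NZ"),
               acceptor = serial_of("Sc-1", "N9"),
               state = c("B", "Ts", "I"), p = c(0.99, 0.0, 0.997)),
    data.frame(donor = serial_of("LIG", "N1"),
               acceptor = serial_of("THR", "OG"),
               state = c("B", "Ts", "I"), p = c(0.0, 0.0, 0.36)))

  ## fluctuation sigmas: quiet complex, mobile scissile +1/+2 bases; atoms
  ## whose geometry is overridden by an H-bond pair stay tight so the
  ## Bernoulli occupancy is not smeared across the detection cutoff
  sigma <- rep(0.01, nrow(topo))
  mobile <- which(topo$group == "base" & topo$strand == "scissile" &
                    topo$base_position >= 1L)
  sigma[mobile] <- 0.04
  hb_atoms <- unique(c(occupancy$donor, occupancy$acceptor,
                       topo$donor_hydrogen[occupancy$donor]))
  sigma[hb_atoms[!is.na(hb_atoms)]] <- 0.005
  occupancy <- occupancy[occupancy$state %in% states, , drop = FALSE]
  seq_states <- rep(names(frames_per_state), frames_per_state)
  mock_complex_spec(topo, states, occupancy, sigma, seq_states, seed)
}
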