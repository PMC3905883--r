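## Persistence of mock topologies and trajectories: PDB (via bio3d) with a
## plain-text sidecar table carrying the annotations PDB cannot hold
## (groups, strands, donor/acceptor typing), and multi-frame XYZ with the
## frame time on the comment line.  Coordinates are nm internally and
## Angstrom inside the PDB, per that format's convention.

#' Write a mock topology as PDB plus an annotation sidecar
#'
#' The PDB carries names, residues and mean coordinates (in Angstrom); the
#' sidecar `<path>.annot.tsv` carries group labels, base positions,
#' strands, donor/acceptor flags and donor-hydrogen links, so that
#' [read_topology_pdb()] round-trips the full topology.
#'
#' @param topology a [complex_topology()].
#' @param path output PDB path.
#' @export
write_topology_pdb <- function(topology, path) {
  xyz <- as.vector(t(as.matrix(topology[, c("x", "y", "z")]) * 10))
  ## PDB resid must be plain alphanumerics; the sidecar keeps the real
  ## residue names (with signed base positions), so collisions here are fine
  resid <- toupper(gsub("[^A-Za-z0-9]", "", topology$residue_name))
  resid <- substr(resid, 1L, 3L)
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = rep("ATOM", nrow(topology)),
                   eleno = topology$serial,
                   elety = topology$name,
                   resno = topology$residue_id,
                   resid = resid,
                   elesy = topology$element)
  annot <- topology[, c("serial", "name", "element", "group",
                        "base_position", "strand", "residue_name",
                        "residue_id", "is_donor", "is_acceptor",
                        "donor_hydrogen")]
  write.table(annot, paste0(path, ".annot.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Read a mock topology written by [write_topology_pdb()]
#'
#' @param path PDB path (the `<path>.annot.tsv` sidecar must sit next to
#'   it).
#' @return A [complex_topology()] with coordinates in nm.
#' @export
read_topology_pdb <- function(path) {
  sidecar <- paste0(path, ".annot.tsv")
  if (!file.exists(sidecar))
    stop("annotation sidecar not found: ", sidecar)
  pdb <- bio3d::read.pdb(path)
  annot <- read.table(sidecar, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE)
  xyz <- matrix(pdb$xyz, ncol = 3L, byrow = TRUE) / 10
  atoms <- data.frame(
    name = annot$name, element = annot$element, group = annot$group,
    base_position = annot$base_position, strand = annot$strand,
    residue_name = annot$residue_name, residue_id = annot$residue_id,
    is_donor = annot$is_donor, is_acceptor = annot$is_acceptor,
    donor_hydrogen = annot$donor_hydrogen,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L])
  complex_topology(atoms)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Standard XYZ blocks (atom count, comment, one `name x y z` line per
#' atom); coordinates in nm and the frame time recorded on the comment
#' line as `t= <ps> ps`.
#'
#' @param traj a `mock_trajectory` or list of frames.
#' @param topology a [complex_topology()] (names); optional for
#'   `mock_trajectory`.
#' @param path output file.
#' @param times per-frame times, ps (default from the trajectory).
#' @export
write_xyz_trajectory <- function(traj, path, topology = NULL,
                                 times = NULL) {
  if (inherits(traj, "mock_trajectory")) {
    if (is.null(topology)) topology <- traj$topology
    if (is.null(times)) times <- traj$times
  }
  frames <- .traj_frames(traj)
  if (is.null(times)) times <- seq_along(frames)
  names <- if (!is.null(topology)) topology$name
           else rep("X", nrow(frames[[1L]]))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    xyz <- frames[[f]]
    writeLines(c(as.character(nrow(xyz)),
                 sprintf("t= %.6f ps (coordinates in nm)", times[f]),
                 sprintf("%-4s %14.8f %14.8f %14.8f", names,
                         xyz[, 1L], xyz[, 2L], xyz[, 3L])), con)
  }
}

#' Read a multi-frame XYZ trajectory
#'
#' @param path file written by [write_xyz_trajectory()].
#' @return List with `frames` (list of n_atoms x 3 matrices, nm), `times`
#'   (ps; NA when the comment carries no time) and `names`.
#' @export
read_xyz_trajectory <- function(path) {
  lines <- readLines(path)
  frames <- list(); times <- numeric(0); names <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop("malformed XYZ at line ", i, ": expected atom count")
    if (i + 1L + n > length(lines))
      stop("truncated XYZ frame starting at line ", i)
    comment <- lines[i + 1L]
    tm <- regmatches(comment,
                     regexec("t=\\s*([-0-9.eE+]+)", comment))[[1L]]
    times <- c(times, if (length(tm) == 2L) as.numeric(tm[2L]) else NA_real_)
    block <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(block), "\\s+")
    if (any(lengths(parts) < 4L))
      stop("malformed XYZ coordinate line in frame starting at line ", i)
    if (is.null(names)) names <- vapply(parts, `[`, character(1L), 1L)
    xyz <- matrix(as.numeric(unlist(lapply(parts, `[`, 2:4))),
                  ncol = 3L, byrow = TRUE)
    frames <- c(frames, list(xyz))
    i <- i + 2L + n
  }
  list(frames = frames, times = times, names = names)
}
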