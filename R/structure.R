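## Per-state structural statistics on trajectories: mass-weighted RMSF,
## geometric hydrogen-bond detection and per-state occupancies, Kabsch
## superposition RMSD, gromos conformational clustering, and the nick-width
## distance between the base groups flanking the cleavage site.

.traj_frames <- function(traj) {
  if (inherits(traj, "mock_trajectory")) traj$frames else traj
}

## Mass-weighted least-squares superposition of `mob` onto `ref`
## (n x 3 matrices); returns the transformed mobile coordinates.
.superpose <- function(mob, ref, w) {
  w <- w / sum(w)
  cm <- colSums(mob * w); cr <- colSums(ref * w)
  a <- sweep(mob, 2L, cm); b <- sweep(ref, 2L, cr)
  sv <- svd(crossprod(a * w, b))
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sweep(a %*% rot, 2L, cr, "+")
}

## Fit `frame` onto `ref` by mass-weighted Kabsch over `fit_selection`,
## then apply the resulting rigid transform to the whole frame.
.apply_fit <- function(frame, ref, fit_selection, masses) {
  w <- masses[fit_selection] / sum(masses[fit_selection])
  mob <- frame[fit_selection, , drop = FALSE]
  tgt <- ref[fit_selection, , drop = FALSE]
  cm <- colSums(mob * w); cr <- colSums(tgt * w)
  sv <- svd(crossprod(sweep(mob, 2L, cm) * w, sweep(tgt, 2L, cr)))
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sweep(sweep(frame, 2L, cm) %*% rot, 2L, cr, "+")
}

.check_superposable <- function(xyz) {
  if (nrow(xyz) < 3L)
    stop("superposition needs >= 3 atoms")
  s <- svd(sweep(xyz, 2L, colMeans(xyz)))$d
  if (s[2L] < 1e-10 * max(s[1L], 1e-300))
    stop("superposition underdetermined: atoms are collinear")
}

#' Mass-weighted RMSD after optimal superposition
#'
#' Least-squares (Kabsch) superposition of frame `a` onto frame `b` using
#' the selected atoms with mass weights, followed by the mass-weighted root
#' mean square deviation.  Symmetric in its arguments and zero iff the two
#' selections are congruent.
#'
#' @param frame_a,frame_b coordinate matrices (n_atoms x 3, nm).
#' @param selection atom indices used for fitting and deviation (default
#'   all).
#' @param masses per-atom masses, amu.
#' @param fit superpose before measuring (default TRUE).
#' @return RMSD in nm.
#' @export
rmsd_superposed <- function(frame_a, frame_b, selection = NULL,
                            masses = NULL, fit = TRUE) {
  if (is.null(selection)) selection <- seq_len(nrow(frame_a))
  if (is.null(masses)) masses <- rep(1, nrow(frame_a))
  if (nrow(frame_a) != nrow(frame_b))
    stop("frames have different atom counts")
  a <- frame_a[selection, , drop = FALSE]
  b <- frame_b[selection, , drop = FALSE]
  w <- masses[selection]
  if (fit) {
    .check_superposable(a)
    .check_superposable(b)
    a <- .superpose(a, b, w)
  }
  sqrt(sum(w * rowSums((a - b)^2)) / sum(w))
}

#' Per-residue mass-weighted RMSF
#'
#' Root-mean-square fluctuation about the per-atom time-average position:
#' for each residue, `sqrt( sum_i m_i <|r_i(t) - <r_i>|^2> / sum_i m_i )`
#' over its atoms.  By default each frame is first least-squares superposed
#' onto the first frame (mass-weighted, over `fit_selection`), so that
#' rigid-body drift does not inflate the fluctuations; `fit = FALSE` gives
#' the raw fluctuations.
#'
#' @param traj a `mock_trajectory` or list of coordinate matrices (>= 2
#'   frames).
#' @param topology a [complex_topology()] (provides masses and residues);
#'   optional when `traj` is a `mock_trajectory`.
#' @param selection atom indices to report on (default all).
#' @param fit superpose frames onto the first frame before measuring.
#' @param fit_selection atoms used for the superposition (default all).
#' @return Data frame `residue_id`, `residue_name`, `rmsf` (nm).
#' @export
rmsf <- function(traj, topology = NULL, selection = NULL, fit = TRUE,
                 fit_selection = NULL) {
  if (inherits(traj, "mock_trajectory") && is.null(topology))
    topology <- traj$topology
  frames <- .traj_frames(traj)
  if (length(frames) < 2L)
    stop("RMSF is undefined for a single frame")
  n_atoms <- nrow(frames[[1L]])
  if (is.null(selection)) selection <- seq_len(n_atoms)
  if (is.null(fit_selection)) fit_selection <- seq_len(n_atoms)
  masses <- topology$mass
  if (fit) {
    ref <- frames[[1L]]
    .check_superposable(ref[fit_selection, , drop = FALSE])
    frames <- lapply(frames, function(fr)
      .apply_fit(fr, ref, fit_selection, masses))
  }
  arr <- simplify2array(frames)              # n_atoms x 3 x n_frames
  mean_pos <- apply(arr, c(1L, 2L), mean)
  dev2 <- apply((arr - as.vector(mean_pos))^2, c(1L, 3L), sum)
  msf_atom <- rowMeans(dev2)                 # per-atom <|r - <r>|^2>
  sel <- selection
  rid <- topology$residue_id[sel]
  out <- do.call(rbind, lapply(split(seq_along(sel), rid), function(k) {
    idx <- sel[k]
    data.frame(residue_id = topology$residue_id[idx[1L]],
               residue_name = topology$residue_name[idx[1L]],
               rmsf = sqrt(sum(masses[idx] * msf_atom[idx]) /
                             sum(masses[idx])))
  }))
  out <- out[order(out$residue_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Geometric hydrogen-bond criteria
#'
#' @param dist_cutoff donor-acceptor distance cutoff, nm (default 0.35,
#'   the g_hbond convention).
#' @param angle_cutoff hydrogen-donor-acceptor angle cutoff, degrees
#'   (default 30).
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(dist_cutoff = 0.35, angle_cutoff = 30) {
  if (dist_cutoff <= 0 || angle_cutoff <= 0)
    stop("cutoffs must be > 0")
  structure(list(dist_cutoff = dist_cutoff, angle_cutoff = angle_cutoff),
            class = "hbond_criteria")
}

## candidate donor/acceptor pairs from a topology; donors lacking a bound
## hydrogen are skipped with a warning
.hbond_pairs <- function(topology) {
  donors <- which(topology$is_donor)
  no_h <- donors[is.na(topology$donor_hydrogen[donors])]
  if (length(no_h) > 0L) {
    warning("skipping donor(s) without an attached hydrogen: ",
            paste(topology$name[no_h], collapse = ", "))
    donors <- setdiff(donors, no_h)
  }
  acceptors <- which(topology$is_acceptor)
  if (length(donors) == 0L || length(acceptors) == 0L)
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0)))
  g <- expand.grid(donor = donors, acceptor = acceptors,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[g$donor != g$acceptor, , drop = FALSE]
  ## no bonds within the same residue
  g <- g[topology$residue_id[g$donor] != topology$residue_id[g$acceptor], ,
         drop = FALSE]
  g$hydrogen <- topology$donor_hydrogen[g$donor]
  g <- g[order(g$donor, g$acceptor), c("donor", "hydrogen", "acceptor")]
  rownames(g) <- NULL
  g
}

## vectorized geometric criterion for a set of pairs in one frame
.hbond_present <- function(frame, pairs, criteria) {
  if (nrow(pairs) == 0L) return(logical(0))
  dvec <- frame[pairs$acceptor, , drop = FALSE] -
    frame[pairs$donor, , drop = FALSE]
  dist <- sqrt(rowSums(dvec^2))
  hvec <- frame[pairs$hydrogen, , drop = FALSE] -
    frame[pairs$donor, , drop = FALSE]
  cosang <- rowSums(dvec * hvec) /
    pmax(dist * sqrt(rowSums(hvec^2)), 1e-300)
  ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  dist <= criteria$dist_cutoff & ang <= criteria$angle_cutoff
}

#' Detect hydrogen bonds in one frame
#'
#' A donor/acceptor pair is reported when the donor-acceptor distance is
#' within the cutoff and the hydrogen-donor-acceptor angle within the
#' angle cutoff; output is ordered by (donor, acceptor).
#'
#' @param frame coordinate matrix (n_atoms x 3, nm).
#' @param topology a [complex_topology()] marking donors (with bound
#'   hydrogens) and acceptors.
#' @param criteria an [hbond_criteria()].
#' @return Data frame `donor`, `hydrogen`, `acceptor` (atom serials).
#' @export
detect_hbonds <- function(frame, topology, criteria = hbond_criteria()) {
  pairs <- .hbond_pairs(topology)
  keep <- .hbond_present(frame, pairs, criteria)
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-state hydrogen-bond percentages of existence
#'
#' For every candidate donor/acceptor pair and every state, the percentage
#' of that state's frames in which the geometric criterion holds.
#' Unassigned frames are excluded, and only pairs exceeding the reporting
#' threshold in at least one state are kept (the "present in >25% of
#' conformations in at least one equilibrium state" filter).
#'
#' @param traj a `mock_trajectory` or list of frames.
#' @param topology a [complex_topology()]; optional for `mock_trajectory`.
#' @param states per-frame state labels (character, `NA` = unassigned) or
#'   a `state_assignment` from [assign_frames()].
#' @param criteria an [hbond_criteria()].
#' @param report_threshold keep pairs with any state percentage strictly
#'   above this value (default 25).
#' @return Data frame of class `hbond_stats`: donor/acceptor atom and
#'   residue names, then one `pct_<state>` column per state and matching
#'   `n_<state>` frame counts.
#' @export
hbond_percentages <- function(traj, topology = NULL, states,
                              criteria = hbond_criteria(),
                              report_threshold = 25) {
  if (inherits(traj, "mock_trajectory") && is.null(topology))
    topology <- traj$topology
  frames <- .traj_frames(traj)
  if (inherits(states, "state_assignment")) states <- states$state
  if (length(states) != length(frames))
    stop("'states' must have one label per frame")
  pairs <- .hbond_pairs(topology)
  state_levels <- unique(states[!is.na(states)])
  if (length(state_levels) == 0L) stop("no assigned frames")

  present <- matrix(FALSE, length(frames), nrow(pairs))
  for (f in seq_along(frames))
    present[f, ] <- .hbond_present(frames[[f]], pairs, criteria)

  n_state <- vapply(state_levels, function(s) sum(states == s & !is.na(states)),
                    integer(1L))
  pct <- sapply(state_levels, function(s) {
    sel <- which(states == s)
    if (length(sel) == 0L) rep(NA_real_, nrow(pairs))
    else 100 * colSums(present[sel, , drop = FALSE]) / length(sel)
  })
  if (is.null(dim(pct))) pct <- matrix(pct, nrow = nrow(pairs))
  keep <- apply(pct, 1L, function(p) any(p > report_threshold, na.rm = TRUE))

  out <- data.frame(
    donor = pairs$donor[keep], acceptor = pairs$acceptor[keep],
    donor_residue = topology$residue_name[pairs$donor[keep]],
    donor_atom = topology$name[pairs$donor[keep]],
    acceptor_residue = topology$residue_name[pairs$acceptor[keep]],
    acceptor_atom = topology$name[pairs$acceptor[keep]])
  for (i in seq_along(state_levels)) {
    out[[paste0("pct_", state_levels[i])]] <- pct[keep, i]
    out[[paste0("n_", state_levels[i])]] <- n_state[i]
  }
  attr(out, "report_threshold") <- report_threshold
  class(out) <- c("hbond_stats", "data.frame")
  out
}

#' gromos conformational clustering
#'
#' Greedy neighbor-counting clustering on the matrix of pairwise superposed
#' RMSDs: the frame with the most neighbors within the cutoff (ties to the
#' lowest frame index) forms a cluster with those neighbors; the cluster is
#' removed and the procedure repeats.  The representative of each cluster
#' is its medoid (the member minimising the summed RMSD to the others).
#'
#' @param traj a `mock_trajectory` or list of frames (>= 1).
#' @param selection atom indices clustered on (default all).
#' @param masses per-atom masses (default: topology masses, else unit).
#' @param cutoff RMSD cutoff, nm (> 0; default 0.1).
#' @return List of class `cluster_result`: `clusters` (list of frame-index
#'   vectors, sizes non-increasing), `representative` (one frame index per
#'   cluster), `rmsd` (full pairwise matrix) and `cutoff`.
#' @export
gromos_cluster <- function(traj, selection = NULL, masses = NULL,
                           cutoff = 0.1) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("'cutoff' must be > 0")
  topology <- if (inherits(traj, "mock_trajectory")) traj$topology else NULL
  frames <- .traj_frames(traj)
  n <- length(frames)
  if (n == 0L) stop("empty trajectory")
  if (is.null(masses))
    masses <- if (!is.null(topology)) topology$mass
              else rep(1, nrow(frames[[1L]]))
  rmat <- matrix(0, n, n)
  for (i in seq_len(n - 1L))
    for (j in seq(i + 1L, n)) {
      r <- rmsd_superposed(frames[[i]], frames[[j]], selection, masses)
      rmat[i, j] <- r; rmat[j, i] <- r
    }
  neigh <- rmat <= cutoff           # includes self on the diagonal
  remaining <- rep(TRUE, n)
  clusters <- list(); reps <- integer(0)
  while (any(remaining)) {
    counts <- rowSums(neigh[, remaining, drop = FALSE]) # neighbors incl self
    counts[!remaining] <- -1L
    center <- which.max(counts)     # ties -> lowest index
    members <- which(remaining & neigh[center, ])
    sub <- rmat[members, members, drop = FALSE]
    reps <- c(reps, members[which.min(rowSums(sub))])
    clusters <- c(clusters, list(members))
    remaining[members] <- FALSE
  }
  structure(list(clusters = clusters, representative = reps,
                 rmsd = rmat, cutoff = cutoff),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", length(x$clusters), "clusters at cutoff",
      x$cutoff, "nm; sizes:",
      paste(lengths(x$clusters), collapse = ", "), "\n")
  invisible(x)
}

#' Nick width: distance between the base groups flanking the cleavage site
#'
#' Distance between the centers of mass of the pooled bases (both strands)
#' at position +1 and at position -1.
#'
#' @param frame coordinate matrix (n_atoms x 3, nm).
#' @param topology a [complex_topology()] with labelled base positions.
#' @return Distance in nm.
#' @export
nick_width <- function(frame, topology) {
  minus <- which(topology$group == "base" & topology$base_position == -1L)
  plus <- which(topology$group == "base" & topology$base_position == 1L)
  if (length(minus) == 0L || length(plus) == 0L)
    stop("topology lacks bases at position -1 and/or +1")
  com_distance(frame, minus, plus, topology$mass)
}

#' Per-state nick-width statistics
#'
#' @param traj a `mock_trajectory` or list of frames.
#' @param topology a [complex_topology()]; optional for `mock_trajectory`.
#' @param states per-frame state labels or a `state_assignment`.
#' @return Data frame `state`, `mean` (nm), `sd` (nm), `n`.
#' @export
nick_width_by_state <- function(traj, topology = NULL, states) {
  if (inherits(traj, "mock_trajectory") && is.null(topology))
    topology <- traj$topology
  frames <- .traj_frames(traj)
  if (inherits(states, "state_assignment")) states <- states$state
  w <- vapply(frames, nick_width, numeric(1L), topology = topology)
  ok <- !is.na(states)
  out <- do.call(rbind, lapply(split(w[ok], states[ok]), function(v)
    data.frame(mean = mean(v), sd = stats::sd(v), n = length(v))))
  out <- cbind(state = rownames(out), out)
  rownames(out) <- NULL
  out
}
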