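## Basin and transition-state analysis on a gridded free-energy surface:
## local minima, steepest-descent basin assignment, frame-to-state
## assignment with an energy cutoff, and minimax minimum-energy paths.

.fes_dims <- function(fes) {
  stopifnot(inherits(fes, "fes_grid"))
  length(fes$spec$min)
}

## neighbor offsets for the 8-connected grid, fixed order (ties are broken
## by this order, matching the brute-force oracles)
.NBR_OFFSETS <- cbind(di = c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
                      dj = c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))

## matrix (n_nodes x 8) of neighbor linear indices, NA outside the grid
.neighbor_index <- function(n1, n2) {
  ij <- cbind(rep(seq_len(n1), n2), rep(seq_len(n2), each = n1))
  out <- matrix(NA_integer_, n1 * n2, 8L)
  for (k in seq_len(8L)) {
    ni <- ij[, 1L] + .NBR_OFFSETS[k, 1L]
    nj <- ij[, 2L] + .NBR_OFFSETS[k, 2L]
    ok <- ni >= 1L & ni <= n1 & nj >= 1L & nj <= n2
    out[ok, k] <- ni[ok] + (nj[ok] - 1L) * n1
  }
  out
}

#' Locate local minima of a free-energy surface
#'
#' A grid node is a minimum when it is strictly lower than all of its 8
#' neighbors (boundary nodes compare their available neighbors).  Minima
#' are returned sorted by energy and labelled `B` (lowest), `I` (second),
#' then `M3`, `M4`, ...
#'
#' @param fes an `fes_grid`.
#' @return Data frame with columns `label`, `node` (linear index), `i`,
#'   `j`, per-CV coordinates and `energy`; zero rows (with a warning) on a
#'   flat surface.
#' @export
find_minima <- function(fes) {
  d <- .fes_dims(fes)
  if (d == 1L) {
    v <- as.numeric(fes$values)
    n <- length(v)
    lower_l <- c(TRUE, v[-1L] < v[-n])
    lower_r <- c(v[-n] < v[-1L], TRUE)
    idx <- which(lower_l & lower_r)
    out <- data.frame(node = idx, i = idx, j = 1L,
                      cv1 = fes$axes[[1L]][idx], energy = v[idx])
  } else {
    v <- fes$values
    n1 <- nrow(v); n2 <- ncol(v)
    nbr <- .neighbor_index(n1, n2)
    vv <- as.numeric(v)
    nv <- matrix(vv[nbr], nrow = length(vv))
    nv[is.na(nbr)] <- Inf
    is_min <- vv < apply(nv, 1L, min)
    idx <- which(is_min)
    out <- data.frame(node = idx,
                      i = ((idx - 1L) %% n1) + 1L,
                      j = ((idx - 1L) %/% n1) + 1L)
    out$cv1 <- fes$axes[[1L]][out$i]
    out$cv2 <- fes$axes[[2L]][out$j]
    out$energy <- vv[idx]
  }
  if (nrow(out) == 0L) {
    warning("no strict local minima found (flat surface?)")
    out$label <- character(0)
    return(out)
  }
  out <- out[order(out$energy), , drop = FALSE]
  lab <- paste0("M", seq_len(nrow(out)))
  if (nrow(out) >= 1L) lab[1L] <- "B"
  if (nrow(out) >= 2L) lab[2L] <- "I"
  out$label <- lab
  rownames(out) <- NULL
  out[, c("label", setdiff(names(out), "label"))]
}

#' Assign every grid node to a basin by steepest descent
#'
#' From each node, repeatedly step to the lowest of the 8 neighbors (only
#' if strictly lower than the current node) until a local minimum is
#' reached; the starting node inherits that minimum's label.  Nodes on
#' exactly flat plateaus, where strict descent stalls at a non-minimum, are
#' labelled `NA` (cannot occur on generic surfaces).
#'
#' @param fes an `fes_grid`.
#' @param minima optional result of [find_minima()] (recomputed if absent).
#' @return List of class `basin_map`: `minima` (data frame) and `labels`
#'   (character vector / matrix over grid nodes).
#' @export
basin_assign <- function(fes, minima = NULL) {
  d <- .fes_dims(fes)
  if (is.null(minima)) minima <- find_minima(fes)
  if (nrow(minima) == 0L) stop("surface has no local minima")
  if (d == 1L) {
    v <- as.numeric(fes$values)
    n <- length(v)
    left <- c(Inf, v[-n]); right <- c(v[-1L], Inf)
    succ <- seq_len(n)
    best <- pmin(left, right)
    go_left <- left <= right & left < v
    go_right <- right < left & right < v
    succ[go_left] <- which(go_left) - 1L
    succ[go_right] <- which(go_right) + 1L
  } else {
    v <- fes$values
    n1 <- nrow(v); n2 <- ncol(v)
    nbr <- .neighbor_index(n1, n2)
    vv <- as.numeric(v)
    nv <- matrix(vv[nbr], nrow = length(vv))
    nv[is.na(nbr)] <- Inf
    kbest <- max.col(-nv, ties.method = "first")
    bestv <- nv[cbind(seq_along(vv), kbest)]
    succ <- seq_along(vv)
    desc <- bestv < vv
    succ[desc] <- nbr[cbind(which(desc), kbest[desc])]
  }
  ## pointer jumping: converge each chain to its fixpoint
  repeat {
    succ2 <- succ[succ]
    if (identical(succ2, succ)) break
    succ <- succ2
  }
  labels <- rep(NA_character_, length(succ))
  m <- setNames(minima$label, as.character(minima$node))
  root_lab <- m[as.character(succ)]
  labels[!is.na(root_lab)] <- root_lab[!is.na(root_lab)]
  if (anyNA(labels))
    warning(sum(is.na(labels)),
            " nodes stalled on flat plateaus and were left unassigned")
  structure(list(minima = minima, labels = labels,
                 dim = if (d == 2L) dim(fes$values) else length(fes$values)),
            class = "basin_map")
}

#' @export
print.basin_map <- function(x, ...) {
  cat("<basin_map>", nrow(x$minima), "minima; basin sizes:\n")
  print(table(x$labels, useNA = "ifany"))
  invisible(x)
}

#' Assign trajectory frames to free-energy states
#'
#' Each frame's CV point is mapped to its nearest grid node's basin label
#' and assigned to that state when its interpolated free energy lies less
#' than `cutoff` kJ/mol above the basin minimum; frames outside the grid or
#' above the cutoff are reported unassigned.
#'
#' @param colvar data frame: `time` plus one column per CV (frame order).
#' @param fes an `fes_grid`.
#' @param basins a `basin_map` from [basin_assign()].
#' @param cutoff energy cutoff above the basin minimum, kJ/mol (> 0;
#'   default 20).
#' @return Data frame of class `state_assignment`: `frame`, `time`,
#'   `state` (`NA` = unassigned) and `delta_f`.
#' @export
assign_frames <- function(colvar, fes, basins, cutoff = 20) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop("'cutoff' must be > 0")
  d <- .fes_dims(fes)
  cvcols <- setdiff(names(colvar), "time")[seq_len(d)]
  x <- as.matrix(colvar[cvcols])
  ax <- fes$axes
  nearest <- function(vals, axis)
    pmin.int(pmax.int(round((vals - axis[1L]) /
                              (axis[2L] - axis[1L])) + 1L, 1L),
             length(axis))
  inside <- x[, 1L] >= fes$spec$min[1L] & x[, 1L] <= fes$spec$max[1L]
  node <- nearest(x[, 1L], ax[[1L]])
  if (d == 2L) {
    inside <- inside & x[, 2L] >= fes$spec$min[2L] &
      x[, 2L] <= fes$spec$max[2L]
    node <- node + (nearest(x[, 2L], ax[[2L]]) - 1L) * length(ax[[1L]])
  }
  if (any(!inside))
    warning(sum(!inside), " frames outside the FES grid left unassigned")
  state <- rep(NA_character_, nrow(x))
  state[inside] <- basins$labels[node[inside]]
  f <- fes_interpolate(fes, x)
  fmin <- setNames(basins$minima$energy, basins$minima$label)
  delta_f <- f - unname(fmin[state])
  drop <- !is.na(delta_f) & delta_f >= cutoff
  state[drop] <- NA_character_
  out <- data.frame(frame = seq_len(nrow(x)),
                    time = if ("time" %in% names(colvar)) colvar$time
                           else NA_real_,
                    state = state, delta_f = delta_f)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("state_assignment", "data.frame")
  out
}

## 8-connected lattice edge list for an n1 x n2 grid (undirected, each once)
.grid_edges <- function(n1, n2) {
  idx <- matrix(seq_len(n1 * n2), n1, n2)
  e_h <- cbind(as.vector(idx[-n1, ]), as.vector(idx[-1L, ]))
  e_v <- cbind(as.vector(idx[, -n2]), as.vector(idx[, -1L]))
  e_d1 <- cbind(as.vector(idx[-n1, -n2]), as.vector(idx[-1L, -1L]))
  e_d2 <- cbind(as.vector(idx[-1L, -n2]), as.vector(idx[-n1, -1L]))
  list(ends = rbind(e_h, e_v, e_d1, e_d2),
       len = c(rep(1, nrow(e_h) + nrow(e_v)),
               rep(sqrt(2), nrow(e_d1) + nrow(e_d2))))
}

#' Topographic prominence of FES minima
#'
#' For each local minimum, the height of the lowest saddle separating it
#' from the global minimum (computed on the minimum spanning tree of the
#' grid graph under the minimax edge weight), minus the minimum's energy.
#' The global minimum gets `Inf`.  Prominence separates genuine basins
#' from the shallow dips left by hill-deposition noise on reconstructed
#' surfaces.
#'
#' @param fes an `fes_grid`.
#' @param minima optional [find_minima()] result.
#' @return The minima data frame with a `prominence` column (kJ/mol).
#' @export
minima_prominence <- function(fes, minima = NULL) {
  d <- .fes_dims(fes)
  if (is.null(minima)) minima <- find_minima(fes)
  if (nrow(minima) == 0L) return(cbind(minima, prominence = numeric(0)))
  v <- as.numeric(fes$values)
  nm <- nrow(minima)
  prom <- rep(Inf, nm)
  if (nm > 1L) {
    ## pairwise minimax saddles between minima
    sad <- matrix(Inf, nm, nm)
    if (d == 1L) {
      for (a in seq_len(nm - 1L)) for (b in seq(a + 1L, nm)) {
        na <- minima$node[a]; nb <- minima$node[b]
        sad[a, b] <- sad[b, a] <- max(v[seq(min(na, nb), max(na, nb))])
      }
    } else {
      n1 <- nrow(fes$values); n2 <- ncol(fes$values)
      eg <- .grid_edges(n1, n2)
      wmax <- pmax(v[eg$ends[, 1L]], v[eg$ends[, 2L]])
      g <- igraph::make_graph(t(eg$ends), n = n1 * n2, directed = FALSE)
      mst <- igraph::mst(g, weights = wmax)
      for (a in seq_len(nm - 1L)) {
        paths <- igraph::shortest_paths(mst, from = minima$node[a],
                                        to = minima$node[seq(a + 1L, nm)],
                                        output = "vpath")$vpath
        for (j in seq_along(paths)) {
          b <- a + j
          sad[a, b] <- sad[b, a] <- max(v[as.integer(paths[[j]])])
        }
      }
    }
    ## prominence: lowest saddle to any strictly lower minimum
    for (k in seq_len(nm)) {
      lower <- which(minima$energy < minima$energy[k])
      if (length(lower) > 0L)
        prom[k] <- min(sad[k, lower]) - minima$energy[k]
    }
  }
  minima$prominence <- prom
  minima
}

#' Significant (deep) minima of a reconstructed FES
#'
#' Filters [find_minima()] by topographic prominence and relabels the
#' survivors by increasing energy (`B`, `I`, `M3`, ...).  On surfaces
#' reconstructed from finitely many hills, the deposition sawtooth leaves
#' shallow spurious dips whose prominence is on the scale of the hill
#' height; genuine basins are separated by barriers many times deeper.
#'
#' @param fes an `fes_grid`.
#' @param prominence_min minimum prominence, kJ/mol (default 4, several
#'   times the 1.0 kJ/mol deposition noise scale).
#' @return Minima data frame (with `prominence`), relabelled.
#' @export
significant_minima <- function(fes, prominence_min = 4) {
  m <- minima_prominence(fes)
  m <- m[m$prominence >= prominence_min, , drop = FALSE]
  if (nrow(m) == 0L) return(m)
  m <- m[order(m$energy), , drop = FALSE]
  lab <- paste0("M", seq_len(nrow(m)))
  if (nrow(m) >= 1L) lab[1L] <- "B"
  if (nrow(m) >= 2L) lab[2L] <- "I"
  m$label <- lab
  rownames(m) <- NULL
  m
}

#' Merge shallow basins into their significant parents
#'
#' Every raw local minimum is attached to the significant minimum it is
#' most easily connected to (the lowest minimax saddle, on the minimum
#' spanning tree of the grid graph; ties to the lower-energy parent), and
#' the basin labels are rewritten accordingly.
#'
#' @param fes an `fes_grid`.
#' @param basins a `basin_map` built from the raw [find_minima()] set.
#' @param sig significant minima from [significant_minima()].
#' @return A `basin_map` whose labels are the significant minima's.
#' @export
merge_basins <- function(fes, basins, sig) {
  if (nrow(sig) == 0L) stop("no significant minima to merge into")
  d <- .fes_dims(fes)
  raw <- basins$minima
  parent <- setNames(character(nrow(raw)), raw$label)
  v <- as.numeric(fes$values)
  if (d == 1L) {
    saddle <- function(a, b) max(v[seq(min(a, b), max(a, b))])
    for (k in seq_len(nrow(raw))) {
      sad <- vapply(sig$node, saddle, numeric(1L), a = raw$node[k])
      best <- order(sad, sig$energy)[1L]
      parent[k] <- sig$label[best]
    }
  } else {
    n1 <- nrow(fes$values); n2 <- ncol(fes$values)
    eg <- .grid_edges(n1, n2)
    wmax <- pmax(v[eg$ends[, 1L]], v[eg$ends[, 2L]])
    g <- igraph::make_graph(t(eg$ends), n = n1 * n2, directed = FALSE)
    mst <- igraph::mst(g, weights = wmax)
    for (k in seq_len(nrow(raw))) {
      paths <- igraph::shortest_paths(mst, from = raw$node[k],
                                      to = sig$node,
                                      output = "vpath")$vpath
      sad <- vapply(paths, function(p) max(v[as.integer(p)]), numeric(1L))
      best <- order(sad, sig$energy)[1L]
      parent[k] <- sig$label[best]
    }
  }
  labels <- unname(parent[basins$labels])
  structure(list(minima = sig, labels = labels, dim = basins$dim),
            class = "basin_map")
}

#' Minimum-energy path between two basins
#'
#' The 8-connected grid path from the `from` minimum to the `to` minimum
#' that minimises the maximum free energy along the path (minimax
#' criterion), with ties broken by the lower path integral of the energy.
#' The minimax saddle is found on the minimum spanning tree of the grid
#' graph (edge weight `max(F_u, F_v)`); the reported path is the lowest
#' energy-integral path within the region below the saddle.
#'
#' @param fes an `fes_grid`.
#' @param basins a `basin_map`.
#' @param from,to basin labels (e.g. `"B"`, `"I"`), or grid node indices
#'   given as numbers.
#' @return Object of class `mep_profile`: data frame `path` (`s` in
#'   \[0, 1\], node indices, CV coordinates, `energy`), `saddle_index`,
#'   `saddle_energy` and `activation` (saddle minus the `from` minimum).
#' @export
minimum_energy_path <- function(fes, basins = NULL, from = "B", to = "I") {
  d <- .fes_dims(fes)
  minima <- if (!is.null(basins)) basins$minima else NULL
  resolve <- function(x) {
    if (is.numeric(x)) return(as.integer(x))
    if (is.null(minima)) stop("labels need a basin map; pass node indices")
    if (!x %in% minima$label) stop("unknown basin label: ", x)
    minima$node[minima$label == x]
  }
  a <- resolve(from)
  b <- resolve(to)
  v <- as.numeric(fes$values)

  if (a == b) {
    path_nodes <- a
  } else if (d == 1L) {
    path_nodes <- seq(a, b)
  } else {
    n1 <- nrow(fes$values); n2 <- ncol(fes$values)
    eg <- .grid_edges(n1, n2)
    wmax <- pmax(v[eg$ends[, 1L]], v[eg$ends[, 2L]])
    g <- igraph::make_graph(t(eg$ends), n = n1 * n2, directed = FALSE)
    mst <- igraph::mst(g, weights = wmax)
    p0 <- igraph::shortest_paths(mst, from = a, to = b, output = "vpath")
    p0 <- as.integer(p0$vpath[[1L]])
    saddle_val <- max(v[p0])
    ## tie-break: lowest energy integral among paths staying <= saddle
    keep <- which(v <= saddle_val + 1e-9)
    rank <- integer(length(v)); rank[keep] <- seq_along(keep)
    ok <- rank[eg$ends[, 1L]] > 0L & rank[eg$ends[, 2L]] > 0L
    sub_ends <- cbind(rank[eg$ends[ok, 1L]], rank[eg$ends[ok, 2L]])
    wint <- eg$len[ok] * (v[eg$ends[ok, 1L]] + v[eg$ends[ok, 2L]]) / 2 +
      1e-9 * eg$len[ok]
    gs <- igraph::make_graph(t(sub_ends), n = length(keep),
                             directed = FALSE)
    ps <- igraph::shortest_paths(gs, from = rank[a], to = rank[b],
                                 weights = wint, output = "vpath")
    path_nodes <- keep[as.integer(ps$vpath[[1L]])]
  }

  if (d == 1L) {
    pi_ <- path_nodes; pj <- rep(1L, length(path_nodes))
    coords <- data.frame(cv1 = fes$axes[[1L]][pi_])
    steps <- abs(diff(pi_))
  } else {
    n1 <- nrow(fes$values)
    pi_ <- ((path_nodes - 1L) %% n1) + 1L
    pj <- ((path_nodes - 1L) %/% n1) + 1L
    coords <- data.frame(cv1 = fes$axes[[1L]][pi_],
                         cv2 = fes$axes[[2L]][pj])
    steps <- sqrt(diff(pi_)^2 + diff(pj)^2)
  }
  s <- c(0, cumsum(steps))
  s <- if (length(path_nodes) > 1L) s / s[length(s)] else 0
  path <- cbind(data.frame(s = s, node = path_nodes, i = pi_, j = pj),
                coords, energy = v[path_nodes])
  saddle_index <- which.max(path$energy)
  structure(list(path = path, from = from, to = to,
                 saddle_index = saddle_index,
                 saddle_energy = path$energy[saddle_index],
                 activation = path$energy[saddle_index] - v[a]),
            class = "mep_profile")
}

#' @export
print.mep_profile <- function(x, ...) {
  cat(sprintf(
    "<mep_profile> %s -> %s: %d nodes, saddle %.3f kJ/mol, dG* = %.3f\n",
    x$from, x$to, nrow(x$path), x$saddle_energy, x$activation))
  invisible(x)
}

#' Activation energy of escape to the exit channel
#'
#' Minimax barrier between the global free-energy minimum (the bound
#' state) and the grid node nearest a point in the exit channel.  For an
#' unbinding surface whose main transition state tops every later barrier,
#' this equals the bound-to-transition-state activation energy without
#' requiring the intermediate basin to be resolved.
#'
#' @param fes an `fes_grid`.
#' @param exit_cv CV coordinates of a point in the exit channel (default
#'   `c(4.35, 0)`: 4.35 nm out, zero contacts).
#' @return List with `activation` (kJ/mol), `saddle_energy` and the
#'   underlying `mep_profile`.
#' @export
escape_barrier <- function(fes, exit_cv = c(4.35, 0)) {
  d <- .fes_dims(fes)
  stopifnot(length(exit_cv) == d)
  v <- as.numeric(fes$values)
  glob <- which.min(v)
  idx <- vapply(seq_len(d), function(k) {
    ax <- fes$axes[[k]]
    which.min(abs(ax - exit_cv[k]))
  }, integer(1L))
  exit_node <- if (d == 1L) idx[1L]
               else idx[1L] + (idx[2L] - 1L) * length(fes$axes[[1L]])
  fake_basins <- structure(
    list(minima = data.frame(label = "B", node = glob, energy = v[glob]),
         labels = NULL, dim = dim(fes$values)),
    class = "basin_map")
  mep <- minimum_energy_path(fes, fake_basins, "B", as.numeric(exit_node))
  list(activation = mep$activation, saddle_energy = mep$saddle_energy,
       mep = mep)
}

#' Barrier between two CV probe points
#'
#' Minimax saddle along the grid path between the nodes nearest two given
#' CV points, referenced to the lowest free energy in the neighbourhood of
#' the start point.  Useful when the basin locations are known a priori
#' (e.g. from a generator) and should not depend on which basin the
#' reconstruction happens to place the global minimum in.
#'
#' @param fes an `fes_grid`.
#' @param from_cv,to_cv CV coordinates of the two probe points.
#' @param ref_radius per-CV half-widths of the reference box around
#'   `from_cv` over which the start free energy is minimised (default: 10%
#'   of each axis range).
#' @return List with `activation`, `saddle_energy`, `ref_energy` and the
#'   `mep_profile`.
#' @export
cv_point_barrier <- function(fes, from_cv, to_cv, ref_radius = NULL) {
  d <- .fes_dims(fes)
  stopifnot(length(from_cv) == d, length(to_cv) == d)
  if (is.null(ref_radius))
    ref_radius <- 0.1 * (fes$spec$max - fes$spec$min)
  node_near <- function(cv) {
    idx <- vapply(seq_len(d), function(k)
      which.min(abs(fes$axes[[k]] - cv[k])), integer(1L))
    if (d == 1L) idx[1L]
    else idx[1L] + (idx[2L] - 1L) * length(fes$axes[[1L]])
  }
  mep <- minimum_energy_path(fes, NULL, as.numeric(node_near(from_cv)),
                             as.numeric(node_near(to_cv)))
  inref <- abs(fes$axes[[1L]] - from_cv[1L]) <= ref_radius[1L]
  v <- fes$values
  ref <- if (d == 1L) min(v[inref])
         else min(v[inref, abs(fes$axes[[2L]] - from_cv[2L]) <=
                          ref_radius[2L]])
  list(activation = mep$saddle_energy - ref,
       saddle_energy = mep$saddle_energy, ref_energy = ref, mep = mep)
}

#' Free-energy profile along a minimum-energy path
#'
#' Two-column table of the normalized reaction coordinate (0 at the start
#' basin, 1 at the path end) and the free energy, suitable for plotting.
#'
#' @param mep an `mep_profile` from [minimum_energy_path()].
#' @return Data frame `s`, `free_energy`; endpoint basin labels and the
#'   saddle energy are attached as attributes.
#' @export
profile_along_path <- function(mep) {
  stopifnot(inherits(mep, "mep_profile"))
  out <- data.frame(s = mep$path$s, free_energy = mep$path$energy)
  attr(out, "from") <- mep$from
  attr(out, "to") <- mep$to
  attr(out, "saddle_energy") <- mep$saddle_energy
  out
}
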