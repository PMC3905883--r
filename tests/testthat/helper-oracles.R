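## Independent oracles used across the suite.  These deliberately avoid the
## package's own code paths: plain loops, recursion and exhaustive search.

## central-difference gradient of a scalar function of a point vector
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    xp <- x; xm <- x
    xp[k] <- xp[k] + h; xm[k] <- xm[k] - h
    (f(xp) - f(xm)) / (2 * h)
  }, numeric(1L))
}

## brute-force coordination number: explicit double loop, explicit formula
cn_brute <- function(frame, a, b, d0, r0, n, m) {
  total <- 0
  for (i in a) for (j in b) {
    r <- sqrt(sum((frame[i, ] - frame[j, ])^2))
    x <- (r - d0) / r0
    s <- if (x <= 0) 1 else (1 - x^n) / (1 - x^m)
    total <- total + s
  }
  total
}

## brute-force bias: term-wise Gaussian summation, one hill at a time
bias_brute <- function(hills, x) {
  d <- sum(grepl("^center_", names(hills)))
  total <- 0
  for (k in seq_len(nrow(hills))) {
    e <- 0
    for (dd in seq_len(d)) {
      c_ <- hills[[paste0("center_", dd)]][k]
      s_ <- hills[[paste0("sigma_", dd)]][k]
      e <- e + (x[dd] - c_)^2 / (2 * s_^2)
    }
    total <- total + hills$height[k] * exp(-e)
  }
  total
}

## neighbor offsets in the same fixed order as the package (ties match)
ORACLE_OFFSETS <- cbind(c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L),
                        c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L))

## recursive steepest descent to a local minimum; returns the linear index
## of the terminal node (memoised)
descend_oracle <- function(v) {
  n1 <- nrow(v); n2 <- ncol(v)
  memo <- matrix(NA_integer_, n1, n2)
  desc <- function(i, j) {
    if (!is.na(memo[i, j])) return(memo[i, j])
    best_v <- Inf; best <- c(NA_integer_, NA_integer_)
    for (k in seq_len(8L)) {
      ni <- i + ORACLE_OFFSETS[k, 1L]; nj <- j + ORACLE_OFFSETS[k, 2L]
      if (ni < 1L || ni > n1 || nj < 1L || nj > n2) next
      if (v[ni, nj] < best_v) { best_v <- v[ni, nj]; best <- c(ni, nj) }
    }
    res <- if (best_v < v[i, j]) desc(best[1L], best[2L])
           else i + (j - 1L) * n1
    memo[i, j] <<- res
    res
  }
  out <- matrix(NA_integer_, n1, n2)
  for (i in seq_len(n1)) for (j in seq_len(n2)) out[i, j] <- desc(i, j)
  out
}

## exhaustive minimax saddle between two nodes: smallest node-value
## threshold t such that a and b are connected in the subgraph {v <= t}
## (8-connectivity, BFS)
minimax_oracle <- function(v, a, b) {
  n1 <- nrow(v); n2 <- ncol(v)
  vv <- as.numeric(v)
  connected_at <- function(t) {
    ok <- vv <= t
    if (!ok[a] || !ok[b]) return(FALSE)
    seen <- rep(FALSE, n1 * n2)
    queue <- a; seen[a] <- TRUE
    while (length(queue) > 0L) {
      cur <- queue[[1L]]; queue <- queue[-1L]
      if (cur == b) return(TRUE)
      ci <- ((cur - 1L) %% n1) + 1L; cj <- ((cur - 1L) %/% n1) + 1L
      for (k in seq_len(8L)) {
        ni <- ci + ORACLE_OFFSETS[k, 1L]; nj <- cj + ORACLE_OFFSETS[k, 2L]
        if (ni < 1L || ni > n1 || nj < 1L || nj > n2) next
        nn <- ni + (nj - 1L) * n1
        if (ok[nn] && !seen[nn]) { seen[nn] <- TRUE; queue <- c(queue, nn) }
      }
    }
    FALSE
  }
  cand <- sort(unique(vv[vv >= max(vv[a], vv[b])]))
  lo <- 1L; hi <- length(cand)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (connected_at(cand[mid])) hi <- mid else lo <- mid + 1L
  }
  cand[lo]
}

## smooth random test surface: a few random Gaussian bumps on a grid
random_smooth_grid <- function(n1, n2, n_bumps = 6L) {
  ax1 <- seq(0, 1, length.out = n1)
  ax2 <- seq(0, 1, length.out = n2)
  v <- matrix(0, n1, n2)
  for (b in seq_len(n_bumps)) {
    cx <- runif(1); cy <- runif(1)
    amp <- runif(1, -1, 1); s <- runif(1, 0.1, 0.35)
    v <- v + amp * outer(exp(-(ax1 - cx)^2 / (2 * s^2)),
                         exp(-(ax2 - cy)^2 / (2 * s^2)))
  }
  v
}

## wrap a plain value matrix as an fes_grid for the landscape operators
as_fes <- function(v, min = c(0, 0), max = c(1, 1)) {
  if (is.matrix(v)) {
    spec <- grid_spec(min, max, dim(v))
    axes <- list(seq(min[1], max[1], length.out = nrow(v)),
                 seq(min[2], max[2], length.out = ncol(v)))
  } else {
    spec <- grid_spec(min[1], max[1], length(v))
    axes <- list(seq(min[1], max[1], length.out = length(v)))
  }
  structure(list(spec = spec, axes = axes, values = v, offset = 0,
                 mode = "standard"),
            class = "fes_grid")
}

## evaluate a toy potential on an exact grid and wrap as fes_grid
potential_on_grid <- function(pot, n) {
  d <- nrow(pot$domain)
  if (d == 1L) {
    ax <- seq(pot$domain[1, 1], pot$domain[1, 2], length.out = n)
    v <- potential_energy(pot, matrix(ax, ncol = 1))
    out <- as_fes(v - min(v), min = pot$domain[1, 1], max = pot$domain[1, 2])
  } else {
    if (length(n) == 1L) n <- rep(n, 2L)
    ax1 <- seq(pot$domain[1, 1], pot$domain[1, 2], length.out = n[1])
    ax2 <- seq(pot$domain[2, 1], pot$domain[2, 2], length.out = n[2])
    v <- matrix(potential_energy(pot, as.matrix(expand.grid(ax1, ax2))),
                n[1], n[2])
    out <- as_fes(v - min(v), min = pot$domain[, 1], max = pot$domain[, 2])
  }
  out
}

## simple rigid motion applied to an n x 3 coordinate matrix
apply_rigid <- function(xyz, angle = 0.7, axis = c(0, 0, 1), shift = c(1, -2, 3)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(xyz %*% t(R), 2, shift, "+")
}

## minimal topology builder for structure tests
tiny_topology <- function(xyz, element = "C", residue_id = seq_len(nrow(xyz)),
                          residue_name = paste0("R", residue_id),
                          group = "residue",
                          is_donor = rep(FALSE, nrow(xyz)),
                          is_acceptor = rep(FALSE, nrow(xyz)),
                          donor_hydrogen = rep(NA_integer_, nrow(xyz)),
                          base_position = rep(NA_integer_, nrow(xyz)),
                          strand = rep(NA_character_, nrow(xyz))) {
  complex_topology(data.frame(
    name = paste0("A", seq_len(nrow(xyz))),
    element = rep_len(element, nrow(xyz)),
    group = rep_len(group, nrow(xyz)),
    base_position = base_position, strand = strand,
    residue_name = rep_len(residue_name, nrow(xyz)),
    residue_id = residue_id,
    is_donor = is_donor, is_acceptor = is_acceptor,
    donor_hydrogen = donor_hydrogen,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]))
}
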