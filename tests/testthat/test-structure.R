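test_that("RMSF reproduces hand-computed fluctuations", {
  ## static trajectory -> zero for all residues
  xyz <- matrix(runif(12), 4, 3)
  topo <- tiny_topology(xyz, residue_id = c(1L, 1L, 2L, 2L))
  frames <- replicate(5, xyz, simplify = FALSE)
  r <- rmsf(frames, topo, fit = FALSE)
  expect_equal(r$rmsf, c(0, 0))
  ## one atom alternating z = 0 / z = 2 over equal frames -> RMSF = 1 nm
  xyz1 <- matrix(0, 1, 3)
  topo1 <- tiny_topology(xyz1)
  frames1 <- lapply(1:10, function(f) matrix(c(0, 0, (f %% 2) * 2), 1, 3))
  r1 <- rmsf(frames1, topo1, fit = FALSE)
  expect_equal(r1$rmsf, 1)
  ## two equal-mass atoms with per-atom RMSFs a and b in one residue:
  ## residue RMSF = sqrt((a^2 + b^2) / 2)
  frames2 <- lapply(1:10, function(f)
    rbind(c(0, 0, (f %% 2) * 2),      # atom RMSF 1
          c(5, 0, (f %% 2) * 4)))     # atom RMSF 2
  topo2 <- tiny_topology(matrix(0, 2, 3), residue_id = c(1L, 1L))
  r2 <- rmsf(frames2, topo2, fit = FALSE)
  expect_equal(r2$rmsf, sqrt((1 + 4) / 2))
  ## a single frame has no defined fluctuation
  expect_error(rmsf(frames1[1], topo1, fit = FALSE), "single frame")
})

test_that("RMSF is translation-invariant and fitting removes rigid drift", {
  set.seed(44)
  xyz <- matrix(runif(30), 10, 3)
  topo <- tiny_topology(xyz, residue_id = rep(1:2, each = 5L))
  frames <- lapply(1:8, function(f) xyz + matrix(rnorm(30, 0, 0.01), 10, 3))
  r0 <- rmsf(frames, topo, fit = FALSE)
  shifted <- lapply(frames, function(fr) sweep(fr, 2, c(1, -2, 0.5), "+"))
  expect_equal(rmsf(shifted, topo, fit = FALSE)$rmsf, r0$rmsf)
  ## per-frame rigid drift inflates raw RMSF; fitting removes it
  drifted <- lapply(seq_along(frames), function(f)
    apply_rigid(frames[[f]], angle = 0.05 * f, shift = c(0.1 * f, 0, 0)))
  expect_gt(mean(rmsf(drifted, topo, fit = FALSE)$rmsf), 3 * mean(r0$rmsf))
  expect_equal(rmsf(drifted, topo, fit = TRUE)$rmsf, r0$rmsf,
               tolerance = 0.25)
})

test_that("hydrogen-bond detection applies both geometric gates", {
  ## D at origin with H along +x; acceptor placed on the x axis
  mk <- function(ax, ay = 0) {
    xyz <- rbind(c(0, 0, 0), c(0.1, 0, 0), c(ax, ay, 0))
    tiny_topology(xyz, element = c("N", "H", "O"),
                  residue_id = c(1L, 1L, 2L),
                  is_donor = c(TRUE, FALSE, FALSE),
                  is_acceptor = c(FALSE, FALSE, TRUE),
                  donor_hydrogen = c(2L, NA, NA))
  }
  crit <- hbond_criteria()
  topo <- mk(0.30)
  hb <- detect_hbonds(as.matrix(topo[, c("x", "y", "z")]), topo, crit)
  expect_identical(nrow(hb), 1L)
  expect_identical(hb$donor, 1L)
  expect_identical(hb$acceptor, 3L)
  ## distance gate at 0.35 nm
  topo2 <- mk(0.36)
  expect_identical(
    nrow(detect_hbonds(as.matrix(topo2[, c("x", "y", "z")]), topo2, crit)),
    0L)
  ## angle gate: H-D-A = 45 degrees at 0.30 nm
  topo3 <- mk(0.30 * cos(45 * pi / 180), 0.30 * sin(45 * pi / 180))
  expect_identical(
    nrow(detect_hbonds(as.matrix(topo3[, c("x", "y", "z")]), topo3, crit)),
    0L)
  ## donor without hydrogen is skipped with a warning
  topo4 <- mk(0.30)
  topo4$donor_hydrogen[1] <- NA_integer_
  expect_warning(
    hb4 <- detect_hbonds(as.matrix(topo4[, c("x", "y", "z")]), topo4, crit),
    "without")
  expect_identical(nrow(hb4), 0L)
  expect_error(hbond_criteria(dist_cutoff = -1), "> 0")
})

test_that("per-state H-bond percentages recover generator occupancies", {
  spec <- default_mock_spec(seed = 99L,
                            frames_per_state = c(B = 6000L, Ts = 200L,
                                                 I = 800L))
  traj <- generate_mock_trajectory(spec)
  hb <- hbond_percentages(traj, states = traj$states)
  ## forced pair: ARG -> In-1 N9 at p = 1.0 in Ts
  arg <- hb[hb$donor_residue == "ARG", ]
  expect_identical(nrow(arg), 1L)
  expect_equal(arg$pct_Ts, 100)
  ## the 0.49-occupancy bound-state pair: within 3 binomial SE
  lys <- hb[hb$donor_residue == "LYS", ]
  se3 <- 3 * sqrt(0.49 * 0.51 / 6000) * 100
  expect_lt(abs(lys$pct_B - 49), se3)
  expect_equal(lys$pct_Ts, 0)
  expect_equal(lys$pct_I, 0)
  ## every detected count is bounded by its state's frame total
  for (s in c("B", "Ts", "I"))
    expect_true(all(hb[[paste0("pct_", s)]] <= 100 &
                      hb[[paste0("pct_", s)]] >= 0))
  ## rows below the reporting threshold everywhere are dropped
  occ <- spec$occupancy
  occ$p[occ$donor == occ$donor[occ$p == 0.49][1]] <- 0.10
  spec2 <- mock_complex_spec(spec$topology, spec$states, occ, 0.005,
                             rep("B", 500), seed = 5L)
  traj2 <- generate_mock_trajectory(spec2)
  hb2 <- hbond_percentages(traj2, states = traj2$states)
  expect_false(any(hb2$donor_residue == "LYS"))
})

test_that("superposed RMSD removes rigid motion and matches a hand-built case", {
  set.seed(17)
  a <- matrix(runif(12), 4, 3)
  masses <- c(12, 1, 16, 14)
  ## identical frames
  expect_equal(rmsd_superposed(a, a, masses = masses), 0)
  ## rigid copy superposes to ~0
  b <- apply_rigid(a)
  expect_lt(rmsd_superposed(a, b, masses = masses), 1e-9)
  ## symmetry
  cfrm <- a + matrix(rnorm(12, 0, 0.1), 4, 3)
  expect_equal(rmsd_superposed(a, cfrm, masses = masses),
               rmsd_superposed(cfrm, a, masses = masses), tolerance = 1e-9)
  ## equal masses: cross-check against the bio3d least-squares fit
  r_pkg <- rmsd_superposed(a, cfrm, masses = rep(1, 4))
  fitted <- suppressWarnings(
    bio3d::fit.xyz(as.vector(t(a)), as.vector(t(cfrm))))
  r_bio <- sqrt(mean(rowSums((matrix(fitted, ncol = 3, byrow = TRUE) - a)^2)))
  expect_equal(r_pkg, r_bio, tolerance = 1e-6)
  ## without fitting, a hand-built displacement gives the direct formula
  d <- rbind(c(0.1, 0, 0), c(0, 0.1, 0), c(0, 0, 0.1), c(0.1, 0.1, 0))
  r_raw <- rmsd_superposed(a, a + d, masses = rep(1, 4), fit = FALSE)
  expect_equal(r_raw, sqrt(mean(rowSums(d^2))))
  ## collinear selections are rejected
  line <- cbind(1:4, 0, 0)
  expect_error(rmsd_superposed(line, line + 0.1, masses = rep(1, 4)),
               "collinear")
})

test_that("gromos clustering follows the greedy neighbor-counting rule", {
  set.seed(23)
  base1 <- matrix(runif(15), 5, 3)
  base2 <- base1
  base2[1, ] <- base2[1, ] + 1   # genuinely different conformation
  jitter <- function(m, s = 0.01) m + matrix(rnorm(15, 0, s), 5, 3)
  ## all frames identical -> one cluster containing all
  same <- replicate(4, base1, simplify = FALSE)
  cl0 <- gromos_cluster(same, cutoff = 0.1)
  expect_identical(length(cl0$clusters), 1L)
  expect_identical(sort(cl0$clusters[[1]]), 1:4)
  ## two well-separated blobs -> exactly the blob membership
  frames <- c(lapply(1:5, function(i) jitter(base1)),
              lapply(1:3, function(i) jitter(base2)))
  cl <- gromos_cluster(frames, cutoff = 0.1)
  expect_identical(length(cl$clusters), 2L)
  expect_identical(sort(cl$clusters[[1]]), 1:5)
  expect_identical(sort(cl$clusters[[2]]), 6:8)
  ## sizes are non-increasing and the representative belongs to its cluster
  expect_true(all(diff(lengths(cl$clusters)) <= 0))
  for (k in seq_along(cl$clusters))
    expect_true(cl$representative[k] %in% cl$clusters[[k]])
  ## exhaustive greedy oracle on small frame sets
  for (rep in 1:5) {
    fr <- lapply(1:7, function(i) jitter(base1, s = 0.05))
    cutoff <- 0.08
    cl2 <- gromos_cluster(fr, cutoff = cutoff)
    ## independent replay of the greedy rule on the same rmsd matrix
    rm <- cl2$rmsd
    remaining <- 1:7
    oracle <- list()
    while (length(remaining) > 0) {
      counts <- vapply(remaining, function(i)
        sum(rm[i, remaining] <= cutoff), integer(1))
      center <- remaining[which.max(counts)]
      members <- remaining[rm[center, remaining] <= cutoff]
      oracle <- c(oracle, list(sort(members)))
      remaining <- setdiff(remaining, members)
    }
    expect_identical(lapply(cl2$clusters, sort), oracle)
  }
})

test_that("nick width measures the -1/+1 base separation", {
  spec <- default_mock_spec()
  topo <- spec$topology
  frame <- as.matrix(topo[, c("x", "y", "z")])
  nw <- nick_width(frame, topo)
  minus <- which(topo$group == "base" & topo$base_position == -1L)
  plus <- which(topo$group == "base" & topo$base_position == 1L)
  expect_equal(nw, com_distance(frame, minus, plus, topo$mass))
  ## rigid motion leaves it unchanged
  expect_equal(nick_width(apply_rigid(frame), topo), nw, tolerance = 1e-9)
  ## constructed geometry: +1 COM at origin, -1 COM 1.2 nm away
  xyz <- rbind(c(0, 0, 0), c(0, 0, 1.2))
  topo2 <- tiny_topology(xyz, group = "base",
                         base_position = c(1L, -1L),
                         strand = c("intact", "intact"))
  expect_equal(nick_width(xyz, topo2), 1.2)
  topo3 <- tiny_topology(xyz, group = "base",
                         base_position = c(2L, -2L),
                         strand = c("intact", "intact"))
  expect_error(nick_width(xyz, topo3), "lacks bases")
})
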