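test_that("find_minima matches exhaustive neighborhood checks", {
  ## toy double well on a grid: exactly two minima
  fes <- potential_on_grid(make_double_well(10, 2), 201L)
  m <- find_minima(fes)
  expect_identical(nrow(m), 2L)
  expect_equal(sort(m$cv1), c(-1, 1), tolerance = 0.02)
  ## monotone plane: one minimum at the corner (boundary rule)
  plane <- as_fes(outer(seq(0, 1, length.out = 12),
                        seq(0, 2, length.out = 12), "+"))
  mp <- find_minima(plane)
  expect_identical(nrow(mp), 1L)
  expect_identical(c(mp$i, mp$j), c(1L, 1L))
  ## negated single-hill bias: brute-force 8-neighborhood oracle
  hills <- data.frame(time = 0.5, center_1 = 0.42, center_2 = 0.58,
                      sigma_1 = 0.2, sigma_2 = 0.2, height = 1, biasf = 1)
  fes2 <- reconstruct_fes(hills, grid_spec(c(0, 0), c(1, 1), 25L))
  m2 <- find_minima(fes2)
  v <- fes2$values
  brute <- integer(0)
  for (i in 1:25) for (j in 1:25) {
    lower <- TRUE
    for (k in seq_len(8)) {
      ni <- i + ORACLE_OFFSETS[k, 1]; nj <- j + ORACLE_OFFSETS[k, 2]
      if (ni < 1 || ni > 25 || nj < 1 || nj > 25) next
      if (v[ni, nj] <= v[i, j]) { lower <- FALSE; break }
    }
    if (lower) brute <- c(brute, i + (j - 1L) * 25L)
  }
  expect_setequal(m2$node, brute)
  ## flat grid: no minima, with a warning
  expect_warning(mf <- find_minima(as_fes(matrix(1, 5, 5))), "flat")
  expect_identical(nrow(mf), 0L)
})

test_that("basin assignment equals the recursive steepest-descent oracle", {
  ## single-minimum bowl: everything labelled with it
  bowl <- as_fes(outer((seq(-1, 1, length.out = 15))^2,
                       (seq(-1, 1, length.out = 15))^2, "+"))
  bb <- basin_assign(bowl)
  expect_true(all(bb$labels == "B"))
  ## double well: the two basins partition the grid
  fes <- potential_on_grid(make_double_well(10, 2), 101L)
  b2 <- basin_assign(fes)
  expect_identical(sum(table(b2$labels)), 101L)
  ## random smooth grids against the recursive oracle
  set.seed(77)
  for (rep in 1:20) {
    v <- random_smooth_grid(12L, 12L)
    fz <- as_fes(v)
    m <- find_minima(fz)
    b <- basin_assign(fz, m)
    oracle_roots <- descend_oracle(v)
    root_label <- setNames(m$label, as.character(m$node))
    expect_identical(b$labels,
                     unname(root_label[as.character(as.integer(oracle_roots))]))
  }
})

test_that("frames are assigned to basins under the energy cutoff", {
  fes <- potential_on_grid(make_double_well(20, 2), 401L)
  basins <- basin_assign(fes)
  colvar <- data.frame(time = c(0.5, 1.0, 1.5, 2.0),
                       cv_1 = c(-1, 1, 0, 5))
  ## frame at a minimum is assigned; the saddle frame (dF = 20) is not;
  ## out-of-grid frames are unassigned with a warning
  expect_warning(st <- assign_frames(colvar, fes, basins, cutoff = 20),
                 "outside")
  expect_identical(st$state[1], "B")
  expect_identical(st$state[2], "I")
  expect_true(is.na(st$state[3]))
  expect_true(is.na(st$state[4]))
  expect_equal(st$delta_f[1], 0, tolerance = 1e-9)
  ## a frame part-way up the wall keeps a positive energy gap
  st2 <- assign_frames(data.frame(time = 1, cv_1 = -0.45), fes, basins)
  expect_true(st2$delta_f > 0)
  expect_error(assign_frames(colvar, fes, basins, cutoff = -1), "> 0")
})

test_that("synthetic state sequences are recovered from basin assignment", {
  pot <- make_unbinding_landscape(barrier_BTs = 20)
  fes <- potential_on_grid(pot, c(301L, 301L))
  basins <- suppressWarnings(basin_assign(fes))
  set.seed(15)
  n <- 400
  truth <- sample(c("B", "I"), n, replace = TRUE)
  ## frames jittered around each basin's minimum
  centers <- list(B = pot$minima$B$cv, I = pot$minima$I$cv)
  cv <- t(vapply(truth, function(s)
    centers[[s]] + c(rnorm(1, 0, 0.05), rnorm(1, 0, 8)), numeric(2)))
  cv[, 2] <- pmax(cv[, 2], 0)
  colvar <- data.frame(time = seq_len(n) * 0.5, cv_1 = cv[, 1],
                       cv_2 = cv[, 2])
  st <- assign_frames(colvar, fes, basins, cutoff = 20)
  ok <- !is.na(st$state)
  expect_gt(mean(st$state[ok] == truth[ok]), 0.95)
  expect_gt(mean(ok), 0.9)
})

test_that("minimum energy path reproduces analytic barriers and the minimax oracle", {
  ## from == to: single node, zero activation
  fes <- potential_on_grid(make_double_well(20, 2), 801L)
  basins <- basin_assign(fes)
  mep0 <- minimum_energy_path(fes, basins, "B", "B")
  expect_identical(nrow(mep0$path), 1L)
  expect_equal(mep0$activation, 0)
  ## analytic double well: barrier recovered within one node's spacing
  mep <- minimum_energy_path(fes, basins, "B", "I")
  expect_equal(mep$activation, 20, tolerance = 0.01)
  expect_equal(mep$saddle_energy, max(mep$path$energy))
  ## random grids: saddle equals the exhaustive minimax oracle
  set.seed(99)
  for (rep in 1:12) {
    v <- random_smooth_grid(13L, 13L)
    v <- v - min(v)
    fz <- as_fes(v)
    m <- find_minima(fz)
    if (nrow(m) < 2) next
    b <- basin_assign(fz, m)
    mepx <- minimum_energy_path(fz, b, "B", "I")
    oracle <- minimax_oracle(v, m$node[m$label == "B"],
                             m$node[m$label == "I"])
    expect_equal(mepx$saddle_energy, oracle, tolerance = 1e-12)
  }
  expect_error(minimum_energy_path(fes, basins, "B", "Z"), "unknown")
})

test_that("activation energies are non-negative and saddle-symmetric", {
  set.seed(123)
  for (rep in 1:5) {
    v <- random_smooth_grid(15L, 15L)
    v <- v - min(v)
    fz <- as_fes(v)
    m <- find_minima(fz)
    if (nrow(m) < 2) next
    b <- basin_assign(fz, m)
    ab <- minimum_energy_path(fz, b, "B", "I")
    ba <- minimum_energy_path(fz, b, "I", "B")
    expect_gte(ab$activation, 0)
    expect_gte(ba$activation, 0)
    fB <- m$energy[m$label == "B"]; fI <- m$energy[m$label == "I"]
    expect_equal(ab$activation - ba$activation, fI - fB, tolerance = 1e-9)
  }
})

test_that("path profiles carry a normalized monotone reaction coordinate", {
  ## three collinear equally spaced nodes -> s = 0, 0.5, 1
  v <- matrix(5, 7, 7)
  v[2, 4] <- 0; v[3, 4] <- 1; v[4, 4] <- 2
  v[5, 4] <- 4.9; v[6, 4] <- 0.5   # second minimum two steps away
  fz <- as_fes(v)
  m <- find_minima(fz)
  b <- suppressWarnings(basin_assign(fz, m))
  mep <- minimum_energy_path(fz, b, "B", "I")
  expect_equal(mep$path$s[1], 0)
  expect_equal(mep$path$s[nrow(mep$path)], 1)
  expect_true(all(diff(mep$path$s) > 0))
  prof <- profile_along_path(mep)
  expect_equal(max(prof$free_energy), mep$saddle_energy)
  ## F(s = 0) = 0 when the start is the global minimum
  fes <- potential_on_grid(make_double_well(10, 2), 201L)
  basins <- basin_assign(fes)
  prof2 <- profile_along_path(minimum_energy_path(fes, basins, "B", "I"))
  expect_equal(prof2$free_energy[1], 0, tolerance = 1e-9)
  s3 <- minimum_energy_path(fes, basins, "B", "I")$path$s
  expect_true(all(diff(s3) > 0))
})

test_that("prominence filters shallow minima and merge reassigns their basins", {
  ## deep double well plus a tiny dimple inside the B basin
  fes <- potential_on_grid(make_double_well(20, 2), 401L)
  v <- fes$values
  dip <- which.min(abs(fes$axes[[1]] + 0.5))
  v[dip] <- v[dip] - 0.8          # 0.8 kJ/mol dimple on the B flank
  fz <- as_fes(v, min = -2, max = 2)
  m <- find_minima(fz)
  expect_identical(nrow(m), 3L)
  mp <- minima_prominence(fz, m)
  expect_identical(sum(mp$prominence >= 4), 2L)
  sig <- significant_minima(fz, prominence_min = 4)
  expect_identical(nrow(sig), 2L)
  merged <- merge_basins(fz, basin_assign(fz, m), sig)
  expect_setequal(unique(merged$labels), c("B", "I"))
  ## the dimple's nodes end up in the B basin it sits inside
  expect_identical(merged$labels[dip], "B")
})
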