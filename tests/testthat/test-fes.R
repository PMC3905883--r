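test_that("FES reconstruction follows the sign/shift convention", {
  ## single hill at a grid node: F = 0 there, ~height far away
  hills <- data.frame(time = 0.5, center_1 = 0, center_2 = 0,
                      sigma_1 = 0.1, sigma_2 = 0.1, height = 2,
                      biasf = 1)
  fes <- reconstruct_fes(hills, grid_spec(c(-1, -1), c(1, 1), 51L))
  at_center <- fes_interpolate(fes, c(0, 0))
  expect_equal(at_center, 0, tolerance = 1e-9)
  expect_equal(fes_interpolate(fes, c(1, 1)), 2, tolerance = 1e-3)
  expect_equal(min(fes$values), 0)
  expect_error(reconstruct_fes(hills[0, ]), "empty")
})

test_that("reconstruction equals the bias oracle at every node", {
  hills <- local({
    set.seed(21)
    n <- 60
    data.frame(time = seq_len(n) * 0.5,
               center_1 = runif(n, -1, 1), center_2 = runif(n, -1, 1),
               sigma_1 = runif(n, 0.05, 0.3), sigma_2 = runif(n, 0.05, 0.3),
               height = runif(n, 0.2, 1.2), biasf = 1)
  })
  spec <- grid_spec(c(-1.5, -1.5), c(1.5, 1.5), 31L)
  fes <- reconstruct_fes(hills, spec)
  nodes <- as.matrix(expand.grid(fes$axes[[1]], fes$axes[[2]]))
  oracle <- bias_value(hills, nodes)
  ## -F + shift equals the bias everywhere
  expect_equal(as.numeric(-(fes$values + fes$offset)), oracle,
               tolerance = 1e-10)
})

test_that("well-tempered FES is the standard one scaled by gamma/(gamma-1)", {
  set.seed(4)
  hills <- data.frame(time = (1:20) * 0.5, center_1 = runif(20),
                      sigma_1 = 0.1, height = runif(20, 0.1, 1),
                      biasf = 10)
  spec <- grid_spec(-0.5, 1.5, 101L)
  f_std <- reconstruct_fes(hills, spec, mode = "standard")
  f_wt <- reconstruct_fes(hills, spec, mode = "well_tempered")
  pre_std <- f_std$values + f_std$offset
  pre_wt <- f_wt$values + f_wt$offset
  expect_equal(pre_wt, pre_std * 10 / 9, tolerance = 1e-12)
})

test_that("FES linearity over concatenated hill lists", {
  h1 <- data.frame(time = (1:10) * 0.5, center_1 = runif(10), sigma_1 = 0.2,
                   height = 1, biasf = 1)
  h2 <- data.frame(time = (11:25) * 0.5, center_1 = runif(15), sigma_1 = 0.15,
                   height = 0.5, biasf = 1)
  spec <- grid_spec(-1, 2, 101L)
  pre <- function(h) {
    f <- reconstruct_fes(h, spec)
    f$values + f$offset
  }
  expect_equal(pre(rbind(h1, h2)), pre(h1) + pre(h2), tolerance = 1e-12)
})

test_that("grid refinement changes interpolated values by less than 1%", {
  set.seed(6)
  hills <- data.frame(time = (1:40) * 0.5, center_1 = rnorm(40, 0, 0.4),
                      center_2 = rnorm(40, 0, 0.4),
                      sigma_1 = 0.25, sigma_2 = 0.25,
                      height = runif(40, 0.5, 1), biasf = 1)
  s1 <- grid_spec(c(-2, -2), c(2, 2), 500L)
  s2 <- grid_spec(c(-2, -2), c(2, 2), 1000L)
  f1 <- reconstruct_fes(hills, s1)
  f2 <- reconstruct_fes(hills, s2)
  pts <- matrix(runif(60, -1.8, 1.8), ncol = 2)
  rng <- max(f1$values)
  expect_lt(max(abs(fes_interpolate(f1, pts) - fes_interpolate(f2, pts))),
            0.01 * rng)
})

test_that("escape truncation keeps exactly the pre-escape hills", {
  ## monotone distance crossing 4.0 nm at t = 100 ps with 0.5 ps pace
  colvar <- data.frame(time = seq(0.5, 150, by = 0.5))
  colvar$cv_1 <- 0.04 * colvar$time   # reaches 4.0 exactly at t = 100
  hills <- data.frame(time = seq(0.5, 150, by = 0.5))
  hills$center_1 <- 0.04 * hills$time
  hills$sigma_1 <- 0.1; hills$height <- 1; hills$biasf <- 1
  kept <- truncate_at_escape(colvar, hills, 4.0)
  expect_identical(nrow(kept), 200L)
  expect_lte(max(kept$time), 100)
  ## never reaching the threshold keeps everything
  expect_identical(nrow(truncate_at_escape(colvar, hills, 10)), 300L)
  expect_error(truncate_at_escape(colvar, hills, 0), "> 0")
})

test_that("FES files round-trip through text", {
  set.seed(3)
  hills <- data.frame(time = (1:15) * 0.5, center_1 = runif(15),
                      center_2 = runif(15, 0, 10), sigma_1 = 0.1,
                      sigma_2 = 1, height = 1, biasf = 1)
  fes <- reconstruct_fes(hills, grid_spec(c(0, 0), c(1, 10), c(21L, 16L)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fes(fes, path)
  back <- read_fes(path)
  expect_equal(back$spec$n_points, fes$spec$n_points)
  expect_equal(back$values, fes$values, tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("smoothing removes deposition sawtooth but keeps deep basins", {
  pot <- make_double_well(20, 2)
  base <- potential_on_grid(pot, 401L)
  set.seed(12)
  noisy <- base
  ## spiky noise at the hill-width scale on top of the true profile
  noisy$values <- noisy$values + 1.5 * abs(sin(seq(0, 300, length.out = 401)))
  m_noisy <- find_minima(noisy)
  sm <- fes_smooth(noisy, 0.1)
  m_sm <- significant_minima(sm, prominence_min = 4)
  expect_gt(nrow(m_noisy), 2)
  expect_identical(nrow(m_sm), 2L)
  ## smoothed barrier stays near the true one
  b <- suppressWarnings(basin_assign(sm, significant_minima(sm, 4)))
  mep <- minimum_energy_path(sm, b, "B", "I")
  expect_equal(mep$activation, 20, tolerance = 0.15)
})

test_that("time-averaged FES equals the plain FES for a static hill stream", {
  ## if all checkpoints see the same hills the average is the plain sum
  hills <- data.frame(time = (1:30) * 0.5, center_1 = rep(0.3, 30),
                      sigma_1 = 0.1, height = 1, biasf = 1)
  spec <- grid_spec(-1, 1, 101L)
  plain <- reconstruct_fes(hills, spec)
  avg <- fes_time_average(hills, spec, start_fraction = 1, n_checkpoints = 1L)
  expect_equal(avg$values, plain$values, tolerance = 1e-12)
})
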