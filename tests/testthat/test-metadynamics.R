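random_hills <- function(n, d = 2L, seed = 1) {
  set.seed(seed)
  h <- data.frame(time = seq_len(n) * 0.5)
  for (k in seq_len(d)) h[[paste0("center_", k)]] <- runif(n, -1, 1)
  for (k in seq_len(d)) h[[paste0("sigma_", k)]] <- runif(n, 0.05, 0.3)
  h$height <- runif(n, 0.2, 1.5)
  h$biasf <- 1.0
  h
}

test_that("bias value and gradient match the direct-sum oracle", {
  ## no hills -> zero everywhere
  empty <- random_hills(3)[0, ]
  expect_equal(bias_value(empty, c(0.2, 0.3)), 0)
  ## one hill at its center -> the height
  one <- random_hills(1, seed = 3)
  expect_equal(bias_value(one, c(one$center_1, one$center_2)), one$height)
  ## 50 random hills at random points: term-wise summation oracle
  hills <- random_hills(50, seed = 7)
  set.seed(9)
  for (i in 1:10) {
    x <- runif(2, -1, 1)
    expect_equal(bias_value(hills, x), bias_brute(hills, x),
                 tolerance = 1e-12)
    g_num <- num_grad(function(z) bias_brute(hills, z), x, h = 1e-6)
    expect_equal(as.numeric(bias_gradient(hills, x)), g_num,
                 tolerance = 1e-5)
  }
  ## bias is non-negative everywhere
  set.seed(10)
  pts <- matrix(runif(100, -2, 2), ncol = 2)
  expect_true(all(bias_value(hills, pts) >= 0))
})

test_that("hill heights follow the mode: constant or well-tempered damping", {
  p_std <- meta_params(height = 1.0, widths = 0.1, pace = 0.5)
  ## production heights are 1.0 kJ/mol in standard mode regardless of bias
  expect_equal(next_hill_height(p_std, 0), 1.0)
  expect_equal(next_hill_height(p_std, 57.3), 1.0)
  p_wt <- meta_params(height = 1.0, widths = 0.1, pace = 0.5,
                      mode = "well_tempered", bias_factor = 10,
                      temperature = 300)
  ## first hill undamped
  expect_equal(next_hill_height(p_wt, 0), 1.0)
  ## v = kB (gamma - 1) T  ->  w0 / e
  v <- kB() * 9 * 300
  expect_equal(next_hill_height(p_wt, v), 1.0 / exp(1))
  ## damping is monotone in the deposited bias
  vs <- seq(0, 50, by = 5)
  expect_true(all(diff(next_hill_height(p_wt, vs)) < 0))
  expect_error(meta_params(mode = "well_tempered", bias_factor = 1),
               "bias_factor")
})

test_that("HILLS files round-trip and reject malformed input", {
  hills <- random_hills(100, seed = 11)
  path <- withr::local_tempfile(fileext = ".dat")
  write_hills(hills, path)
  back <- read_hills(path)
  for (col in c("time", "center_1", "center_2", "sigma_1", "sigma_2",
                "height"))
    expect_equal(back[[col]], hills[[col]], tolerance = 1e-9)
  ## header-only file -> empty hills table
  p2 <- withr::local_tempfile(
    lines = "#! FIELDS time center_1 sigma_1 height biasf")
  expect_identical(nrow(read_hills(p2)), 0L)
  ## golden hand-written two-hill file
  p3 <- withr::local_tempfile(lines = c(
    "#! FIELDS time center_1 sigma_1 height biasf",
    "0.5 -0.25 0.1 1.0 1.0",
    "1.0 0.75 0.1 0.5 1.0"))
  g <- read_hills(p3)
  expect_equal(g$center_1, c(-0.25, 0.75))
  expect_equal(g$height, c(1.0, 0.5))
  ## malformed line is reported with its line number
  p4 <- withr::local_tempfile(lines = c(
    "#! FIELDS time center_1 sigma_1 height biasf",
    "0.5 -0.25 0.1 1.0 1.0",
    "1.0 0.75 0.1"))
  expect_error(read_hills(p4), "line 3")
  ## non-monotonic times warn
  p5 <- withr::local_tempfile(lines = c(
    "#! FIELDS time center_1 sigma_1 height biasf",
    "1.0 0.75 0.1 0.5 1.0",
    "0.5 -0.25 0.1 1.0 1.0"))
  expect_warning(read_hills(p5), "monotonic")
})

test_that("run_metadynamics bookkeeping, determinism and guards", {
  pot <- make_double_well(10, 2)
  prm <- meta_params(height = 1.0, widths = 0.1, pace = 0.5)
  run <- run_metadynamics(pot, prm, dt = 0.002, friction = 5,
                          n_steps = 5000, seed = 4, x0 = -1)
  ## hill count = floor(n_steps * dt / pace)
  expect_identical(nrow(run$hills), 5000L %/% 250L)
  expect_equal(run$hills$time, seq_len(20) * 0.5)
  expect_equal(unique(run$hills$height), 1.0)
  ## bit-for-bit reproducibility under the same seed
  run2 <- run_metadynamics(pot, prm, dt = 0.002, friction = 5,
                           n_steps = 5000, seed = 4, x0 = -1)
  expect_identical(run$colvar, run2$colvar)
  expect_identical(run$hills, run2$hills)
  run3 <- run_metadynamics(pot, prm, dt = 0.002, friction = 5,
                           n_steps = 5000, seed = 5, x0 = -1)
  expect_false(identical(run$colvar, run3$colvar))
  ## pace must be a multiple of dt
  expect_error(run_metadynamics(pot, meta_params(pace = 0.5), dt = 0.003,
                                n_steps = 100),
               "multiple")
})

test_that("zero-temperature damped dynamics relaxes into a minimum", {
  pot <- make_double_well(10, 2)
  prm <- meta_params(height = 1e-15, widths = 0.1, pace = 10)
  run <- run_metadynamics(pot, prm, dt = 0.002, friction = 20,
                          temperature = 0, n_steps = 20000, seed = 1,
                          x0 = -0.4, record_stride = 100L)
  final <- run$x_final
  expect_equal(final, -1, tolerance = 1e-3)
  e <- potential_energy(pot, matrix(run$colvar$cv_1, ncol = 1))
  ## overdamped descent: energy decreases to the well floor
  expect_lt(e[length(e)], 1e-5)
  expect_true(all(diff(e) < 1e-6))
})

test_that("unbiased Langevin in a harmonic well satisfies equipartition", {
  pot <- make_harmonic_well(k = 100, center = 0, halfwidth = 2)
  prm <- meta_params(height = 1e-15, widths = 0.1, pace = 1000)
  run <- run_metadynamics(pot, prm, dt = 0.002, friction = 10,
                          temperature = 300, n_steps = 2e5, seed = 3,
                          x0 = 0, record_stride = 10L)
  v <- var(run$colvar$cv_1)
  expect_equal(v, kB() * 300 / 100, tolerance = 0.08)
})
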