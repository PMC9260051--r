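test_that("nRMSE follows its definition", {
  truth <- matrix(c(10, 20, 30, 40), 2, 2)
  mask <- matrix(c(TRUE, TRUE, TRUE, FALSE), 2, 2)
  expect_equal(nrmse(truth, truth, mask)$value_pct, 0)
  expect_equal(nrmse(2 * truth, truth, mask)$value_pct, 100)
  est <- truth + 5
  expected <- 100 * sqrt(3 * 25) / sqrt(10^2 + 20^2 + 30^2)
  expect_equal(nrmse(est, truth, mask)$value_pct, expected)
  expect_error(nrmse(truth, truth, mask & FALSE), "empty")
  expect_error(nrmse(truth, truth * 0, mask), "zero")
})

test_that("Bland-Altman bias and limits of agreement are correct", {
  a <- c(1, 2, 3, 4)
  expect_equal(bland_altman(a, a),
               list(bias = 0, loa_low = 0, loa_high = 0, sd_diff = 0))
  r <- bland_altman(a, a + 5)
  expect_equal(r$bias, 5)
  expect_equal(r$loa_low, 5)
  expect_equal(r$loa_high, 5)
  r2 <- bland_altman(c(0, 0), c(-1, 1))
  expect_equal(r2$bias, 0)
  expect_equal(r2$loa_high, 1.96 * sqrt(2))
  expect_equal(r2$loa_low, -1.96 * sqrt(2))
  expect_error(bland_altman(1, 1))
})

test_that("variability statistics follow their definitions", {
  expect_equal(variability_stats(c(40, 40, 40), c(3, 5, 4))$intersubject, 0)
  expect_equal(variability_stats(c(40, 50), c(3, 5))$intersubject,
               sd(c(40, 50)))
  expect_equal(variability_stats(c(40, 50), c(3, 5))$intrasubject, 4)
  expect_error(variability_stats(40, 3))
})

test_that("the study driver emits one row per cell and is reproducible", {
  tab <- run_simulation_study(
    variants = list(list(n_heartbeats = 5L, window_ms = 50)),
    noise_levels = c(0, 0.1), methods = "direct", matrix = 32L,
    seed = 4L, dict_t1_step = 100, dict_t2_step = 25,
    spiral_dwell_us = 20, verbose = FALSE)
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$method, c("direct", "direct"))
  expect_true(all(tab$t1_nrmse > 0))
  tab2 <- run_simulation_study(
    variants = list(list(n_heartbeats = 5L, window_ms = 50)),
    noise_levels = c(0, 0.1), methods = "direct", matrix = 32L,
    seed = 4L, dict_t1_step = 100, dict_t2_step = 25,
    spiral_dwell_us = 20, verbose = FALSE)
  expect_identical(tab$t1_nrmse, tab2$t1_nrmse)
})

test_that("parameter maps round-trip through NIfTI", {
  maps <- structure(list(
    t1_map = matrix(runif(64, 300, 2000), 8, 8),
    t2_map = matrix(runif(64, 10, 200), 8, 8),
    m0_map = matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8),
    background = matrix(FALSE, 8, 8)
  ), class = "cmrf_parameter_maps")
  pre <- tempfile()
  files <- write_maps_nifti(maps, pre)
  expect_true(all(file.exists(files)))
  back <- RNifti::readNifti(files["t1"])
  expect_equal(as.vector(back), as.vector(maps$t1_map), tolerance = 1e-6)
  unlink(files)
})
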