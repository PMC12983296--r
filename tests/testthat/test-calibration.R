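tiny_cal_axis <- function() spectral_axis(256, 3200, 800, 3)

test_that("estimate_snr uses the recorded sigma or a robust noise floor", {
  # short t2 so the noiseless baseline is smooth (no truncation sidelobes)
  ser <- simulate_echo_series(doublet_system(8, 0.05), tiny_cal_axis())
  noisy <- add_noise(ser, 100, 3)
  # recorded-sigma bypass: peak of the stored series over its known sigma
  expect_equal(estimate_snr(noisy), 100, tolerance = 0.05)

  blind <- noisy
  blind$noise_sigma <- NA_real_                    # force the robust estimator
  est <- estimate_snr(blind)
  expect_gt(est, 70); expect_lt(est, 140)

  expect_gt(estimate_snr(ser), 1e6)                # noiseless, capped
  zero <- ser
  zero$spectra <- lapply(ser$spectra, function(s)
    pureshiftnn:::new_spectrum(s$axis, numeric(256)))
  expect_error(estimate_snr(zero), "all-zero")
})

test_that("calibration curve interpolation, clamping and serialization", {
  curve <- pureshiftnn:::new_calibration_curve(c(20, 200, 2000, 2e4),
                                               c(2, 1.5, 1.2, 1.0))
  # exact at grid nodes, log-linear between
  expect_equal(calibration_factor(curve, 200), 1.5)
  expect_equal(calibration_factor(curve, sqrt(200 * 2000)), 1.35)
  # outside validity range: warning, nearest edge
  expect_warning(f <- calibration_factor(curve, 10), "outside")
  expect_equal(f, 2)
  expect_warning(f2 <- calibration_factor(curve, 1e6), "outside")
  expect_equal(f2, 1.0)

  path <- tempfile(fileext = ".json")
  write_calibration(curve, path)
  curve2 <- read_calibration(path)
  expect_equal(curve2$snr_grid, curve$snr_grid)
  expect_equal(curve2$correction_factor, curve$correction_factor)
  expect_equal(curve2$valid_range, curve$valid_range)
})

test_that("apply_calibration scales sigma only, exactly once", {
  ax <- tiny_cal_axis()
  res <- pureshiftnn:::new_pure_shift_result(ax, stats::rnorm(256),
                                             rep(0.1, 256))
  unit <- pureshiftnn:::new_calibration_curve(c(20, 1e5), c(1, 1))
  r1 <- apply_calibration(res, unit, 100)
  expect_identical(r1$intensity, res$intensity)
  expect_equal(r1$sigma, res$sigma)
  expect_true(r1$calibrated)
  expect_error(apply_calibration(r1, unit, 100), "already calibrated")

  dbl <- pureshiftnn:::new_calibration_curve(c(20, 1e5), c(2, 2))
  r2 <- apply_calibration(res, dbl, 300)
  expect_equal(r2$sigma, res$sigma * 2)
  expect_identical(r2$intensity, res$intensity)
})

test_that("calibration factors are deterministic and track miscalibration", {
  ax <- tiny_cal_axis()
  cfg <- model_config(n_points = 256L, n_filters = 8L,
                      dilation_schedule = c(1L, 2L, 4L))
  tc <- train_config(n_steps = 40L, batch_size = 2L, learning_rate = 2e-3,
                     seed = 2L, validation_size = 4L, val_every = 20L)
  m <- train(build_model(cfg, seed = 2), tc, axis = ax)$model
  grid <- c(50, 500, 5000)
  c1 <- calibrate_uncertainties(m, grid, n_reps = 3, seed = 8, axis = ax)
  c2 <- calibrate_uncertainties(m, grid, n_reps = 3, seed = 8, axis = ax)
  expect_identical(c1$correction_factor, c2$correction_factor)
  expect_true(all(c1$correction_factor > 0))

  # a model whose sigma is artificially halved needs exactly twice the factor
  m_half <- m
  m_half$params$b_lv <- m_half$params$b_lv - 2 * log(2)
  c_half <- calibrate_uncertainties(m_half, grid, n_reps = 3, seed = 8, axis = ax)
  expect_equal(c_half$correction_factor, 2 * c1$correction_factor,
               tolerance = 1e-6)
  expect_error(calibrate_uncertainties(m, grid, n_reps = 1, seed = 1, axis = ax),
               "n_reps")
})

test_that("coverage_check matches Gaussian 1-sigma mass in the exact case", {
  ax <- tiny_cal_axis()
  truth <- make_pure_shift_target(doublet_system(8, 0.5), ax)
  n <- ax$n_points

  # sigma -> infinity: full coverage; sigma -> 0 with residuals: none
  res_inf <- pureshiftnn:::new_pure_shift_result(ax, truth$values + 1,
                                                 rep(1e12, n))
  expect_equal(coverage_check(res_inf, truth), 1)
  res_zero <- pureshiftnn:::new_pure_shift_result(ax, truth$values + 1,
                                                  rep(1e-12, n))
  expect_equal(coverage_check(res_zero, truth), 0)

  # residuals drawn exactly from N(0, sigma^2): coverage ~ 0.683
  set.seed(31)
  results <- lapply(1:40, function(k) {
    sig <- stats::runif(n, 0.5, 2)
    pureshiftnn:::new_pure_shift_result(ax, truth$values + stats::rnorm(n, 0, sig), sig)
  })
  truths <- rep(list(truth), 40)
  cov <- coverage_check(results, truths)
  expect_equal(as.numeric(cov), 2 * stats::pnorm(1) - 1, tolerance = 0.02)

  # per-bin reporting
  cov2 <- coverage_check(results, truths, bins = rep(c("a", "b"), each = 20))
  by <- attr(cov2, "by_bin")
  expect_equal(sort(by$bin), c("a", "b"))
  expect_true(all(abs(by$coverage - 0.683) < 0.05))
  expect_error(coverage_check(results[1:2], truths[1:3]), "mismatched")
})
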