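test_that("echo schedule enforces its contract and defaults to five delays", {
  sch <- echo_schedule()
  expect_equal(sch$delays, c(0, 0.010, 0.030, 0.050, 0.090))
  expect_error(echo_schedule(c(0.01, 0.03)), "first echo delay")
  expect_error(echo_schedule(c(0, 0.03, 0.03)), "strictly increasing")
})

test_that("doublet echo modulation follows cos(pi J T) exp(-T/t2)", {
  ax <- test_axis(512)
  for (j in c(4, 10, 16)) {
    for (t2 in c(0.4, 1e5)) {
      sys <- doublet_system(j, t2)
      ser <- simulate_echo_series(sys, ax)
      ints <- vapply(ser$spectra, spectrum_integral, numeric(1))
      expect_equal(ints / ints[1],
                   cos(pi * j * ser$schedule$delays) * exp(-ser$schedule$delays / t2),
                   tolerance = 0.01)
    }
  }
  # analytic null: J = 10 Hz at T = 50 ms
  sys <- doublet_system(10, 1e5)
  ser <- simulate_echo_series(sys, ax)
  ints <- vapply(ser$spectra, spectrum_integral, numeric(1))
  expect_lt(abs(ints[4] / ints[1]), 1e-9)
})

test_that("triplet echo modulation follows cos^2(pi J T)", {
  ax <- test_axis(512)
  # t2 short enough that the FID decays within the acquisition window, so the
  # regional integral is free of truncation sidelobes
  t2 <- 0.05
  sys <- triplet_system(7, t2)
  ser <- simulate_echo_series(sys, ax)
  # integrate only the triplet spin's region (its partners resonate > 1 ppm away)
  region <- abs(axis_ppm(ax) - sys$shifts[1]) < 0.5
  ints <- vapply(ser$spectra, function(s) sum(s$values[region]), numeric(1))
  Tt <- ser$schedule$delays
  expect_lt(max(abs(ints / ints[1] - cos(pi * 7 * Tt)^2 * exp(-Tt / t2))), 0.01)
})

test_that("T = 0 series entry equals the conventional spectrum", {
  ax <- test_axis(512)
  sys <- random_spin_system(7)
  ser <- simulate_echo_series(sys, ax)
  one <- simulate_echo_series(sys, ax, echo_schedule(0))
  expect_equal(ser$spectra[[1]]$values, one$spectra[[1]]$values)
})

test_that("aliasing and invalid relaxation are rejected", {
  ax <- test_axis(512)
  outside <- spin_system(9.0)   # 9 ppm is outside a 4 ppm window centred at 3
  expect_error(simulate_echo_series(outside, ax), "aliasing|window")
  expect_error(make_pure_shift_target(outside, ax), "window")
  expect_error(spin_system(2.5, t2 = 0), "t2")
})

test_that("pure-shift target is one singlet per spin with conserved integral", {
  ax <- test_axis(1024)
  # two-spin J = 8: target has exactly two maxima, at the chemical shifts
  sys <- doublet_system(8, 0.7)
  tgt <- make_pure_shift_target(sys, ax)
  ppm <- axis_ppm(ax)
  v <- tgt$values
  locmax <- which(diff(sign(diff(v))) == -2) + 1L
  locmax <- locmax[v[locmax] > 0.1 * max(v)]
  expect_length(locmax, 2)
  expect_equal(sort(ppm[locmax]), sys$shifts, tolerance = 0.01)

  # a system with no couplings: target identical to its T = 0 spectrum
  sys0 <- spin_system(c(2.2, 3.8), t2 = c(0.5, 1.2))
  ser0 <- simulate_echo_series(sys0, ax)
  expect_equal(make_pure_shift_target(sys0, ax)$values, ser0$spectra[[1]]$values,
               tolerance = 1e-12)

  # integral conservation across random systems
  for (seed in 1:20) {
    sys <- random_spin_system(seed)
    ser <- suppressWarnings(simulate_echo_series(sys, ax))
    expect_equal(spectrum_integral(make_pure_shift_target(sys, ax)),
                 spectrum_integral(ser$spectra[[1]]), tolerance = 0.005)
  }
})

test_that("add_noise is seeded, scaled to the T=0 peak, and records sigma", {
  ax <- test_axis(512)
  sys <- doublet_system(8, 0.5)
  ser <- simulate_echo_series(sys, ax)

  # vanishing-noise limit
  hi <- add_noise(ser, 1e9, 1)
  expect_lt(max(abs(series_matrix(hi) - series_matrix(ser))),
            1e-6 * max(series_matrix(ser)))

  # empirical noise sd ~ max/snr over a signal-free region
  lo <- add_noise(ser, 100, 42)
  expect_equal(lo$noise_sigma, max(ser$spectra[[1]]$values) / 100)
  quiet <- which(abs(axis_ppm(ax) - 1.4) < 0.3)   # no resonances around 1.4 ppm
  emp <- stats::sd(lo$spectra[[1]]$values[quiet] - ser$spectra[[1]]$values[quiet])
  expect_equal(emp, lo$noise_sigma, tolerance = 0.1)

  # determinism: same seed, bit-identical
  expect_identical(series_matrix(add_noise(ser, 100, 42)), series_matrix(lo))
  expect_false(identical(series_matrix(add_noise(ser, 100, 43)),
                         series_matrix(lo)))
  expect_error(add_noise(ser, -1, 1), "positive")
})

test_that("random_spin_system is seeded and honours configured ranges", {
  s1 <- random_spin_system(123)
  s2 <- random_spin_system(123)
  expect_identical(s1, s2)
  expect_false(identical(random_spin_system(124), s1))

  cfg <- spin_gen_config()
  njs <- 0; pairs <- 0; coupled <- 0
  for (seed in 1:400) {
    sys <- random_spin_system(seed, cfg)
    n <- length(sys$shifts)
    expect_true(n >= 1 && n <= 12)
    expect_true(all(sys$shifts >= cfg$shift_range[1] &
                      sys$shifts <= cfg$shift_range[2]))
    expect_true(all(sys$t2 >= cfg$t2_range[1] & sys$t2 <= cfg$t2_range[2]))
    js <- abs(sys$couplings[upper.tri(sys$couplings)])
    expect_true(all(js == 0 | (js >= cfg$j_range[1] & js <= cfg$j_range[2])))
    pairs <- pairs + length(js); coupled <- coupled + sum(js > 0)
  }
  # Monte-Carlo estimate of the pair-coupling probability
  expect_equal(coupled / pairs, cfg$p_couple, tolerance = 0.1)
  expect_error(spin_gen_config(j_range = c(5, 1)), "range")
})
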