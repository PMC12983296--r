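test_that("spectral axis grid is monotone and convertible", {
  ax <- test_axis(512)
  hz <- axis_hz(ax)
  expect_length(hz, 512)
  expect_true(all(diff(hz) > 0))
  expect_equal(diff(range(hz)), ax$spectral_width * (1 - 1 / 512))
  expect_equal(ppm_to_hz(hz_to_ppm(123.4, ax), ax), 123.4)
  expect_error(spectral_axis(500), "power of two")
  expect_error(spectral_axis(32), "power of two")
  expect_error(spectral_axis(512, -1), "positive")
})

test_that("spin_system validates its invariants", {
  J <- matrix(c(0, 7, 7, 0), 2, 2)
  expect_s3_class(spin_system(c(1, 2), J), "spin_system")
  Jbad <- matrix(c(0, 7, 6, 0), 2, 2)
  expect_error(spin_system(c(1, 2), Jbad), "symmetric")
  Jdiag <- matrix(c(1, 7, 7, 0), 2, 2)
  expect_error(spin_system(c(1, 2), Jdiag), "diagonal")
  expect_error(spin_system(c(1, 2), J, t2 = c(1, -1)), "t2")
  expect_error(spin_system(c(1, 2), J, intensities = c(1, 0)), "intensities")
})

test_that("multiplet construction follows the weak-coupling tree", {
  # no partners: identity
  sys1 <- spin_system(2.5)
  m <- build_multiplet(1, sys1)
  expect_equal(m$offset, 0)
  expect_equal(m$intensity, 1)

  # two equal partners: binomial 1:2:1 triplet
  m3 <- build_multiplet(1, triplet_system(7))
  expect_equal(m3$offset, c(-7, 0, 7))
  expect_equal(m3$intensity, c(0.25, 0.5, 0.25))

  # unequal partners: doublet of doublets at +/-7/2 +/- 2/2
  J <- matrix(0, 3, 3)
  J[1, 2] <- J[2, 1] <- 7; J[1, 3] <- J[3, 1] <- 2
  sys <- spin_system(c(2.5, 4.0, 4.4), J)
  m4 <- build_multiplet(1, sys)
  expect_equal(m4$offset, c(-4.5, -2.5, 2.5, 4.5))
  expect_equal(m4$intensity, rep(0.25, 4))

  # intensities always sum to 1, and sub-cutoff couplings are ignored
  Jsmall <- matrix(c(0, 0.1, 0.1, 0), 2, 2)
  msmall <- build_multiplet(1, spin_system(c(1, 2), Jsmall))
  expect_equal(msmall$offset, 0)
  expect_error(build_multiplet(5, sys1), "out of range")
})

test_that("multiplets from n equivalent partners are binomial", {
  for (np in 2:6) {
    n <- np + 1L
    J <- matrix(0, n, n)
    J[1, 2:n] <- J[2:n, 1] <- 8
    shifts <- c(1.5, seq(3.5, 4.5, length.out = np))
    m <- build_multiplet(1, spin_system(shifts, J))
    expect_equal(m$intensity, choose(np, 0:np) / 2^np)
    expect_equal(m$offset, (0:np - np / 2) * 8)
  }
})

test_that("semiweak roof correction tilts intensities and conserves total", {
  # Dv = 10 Hz, J = 6 Hz at 800 MHz: tilt factors 1 -/+ 6/sqrt(136)
  sys <- spin_system(c(3.0, 3.0 + 10 / 800), matrix(c(0, 6, 6, 0), 2, 2))
  m <- build_multiplet(1, sys)
  mc <- apply_semiweak_correction(m, 1, sys, 800)
  d <- sqrt(10^2 + 6^2)
  expect_equal(mc$intensity, 0.5 * c(1 - 6 / d, 1 + 6 / d), tolerance = 1e-12)
  # spin 1 is the lower-frequency partner: inner (enhanced) line faces up-field
  expect_gt(mc$intensity[2], mc$intensity[1])
  expect_equal(sum(mc$intensity), 1, tolerance = 1e-9)

  # weak-coupling limit: Dv = 1000 Hz -> within 1% of untilted
  sysw <- spin_system(c(3.0, 3.0 + 1000 / 800), matrix(c(0, 7, 7, 0), 2, 2))
  mw <- apply_semiweak_correction(build_multiplet(1, sysw), 1, sysw, 800)
  expect_true(all(abs(mw$intensity / 0.5 - 1) < 0.01))

  # no coupling: unchanged
  sys0 <- spin_system(c(1, 2))
  m0 <- build_multiplet(1, sys0)
  expect_identical(apply_semiweak_correction(m0, 1, sys0, 800)$intensity,
                   m0$intensity)

  # degenerate inequivalent pair: flagged, correction skipped, warning
  sysd <- spin_system(c(3.0, 3.0), matrix(c(0, 6, 6, 0), 2, 2))
  md <- build_multiplet(1, sysd)
  expect_warning(mdc <- apply_semiweak_correction(md, 1, sysd, 800),
                 "strongly coupled")
  expect_equal(mdc$intensity, md$intensity)
  expect_equal(attr(mdc, "strong_coupled"), 2L)
})

test_that("roof correction conserves intensity on random many-spin systems", {
  for (seed in 1:25) {
    sys <- random_spin_system(seed)
    for (i in seq_along(sys$shifts)) {
      m <- build_multiplet(i, sys)
      mc <- suppressWarnings(apply_semiweak_correction(m, i, sys, 800))
      expect_equal(sum(mc$intensity), 1, tolerance = 1e-9)
    }
  }
})

test_that("exact AB spectrum matches 4x4 Hamiltonian diagonalization", {
  cases <- list(c(5, -5, 6), c(50, -30, 12), c(3, -3, 1), c(200, 100, 9),
                c(8, -2, -7))
  for (cs in cases) {
    got <- exact_two_spin_spectrum(cs[1], cs[2], cs[3])
    ora <- two_spin_hamiltonian_spectrum(cs[1], cs[2], cs[3])
    expect_equal(got$frequency, ora$frequency, tolerance = 1e-9)
    expect_equal(got$intensity, ora$intensity, tolerance = 1e-9)
  }
  # uncoupled limit: two equal lines at the shifts
  g0 <- exact_two_spin_spectrum(12, -8, 0)
  expect_equal(g0$frequency, c(-8, 12))
  expect_equal(g0$intensity, c(0.5, 0.5))
  # equivalent A2 limit: single line, coupling invisible
  ga <- exact_two_spin_spectrum(4, 4, 11)
  expect_equal(ga$frequency, 4)
  expect_equal(ga$intensity, 1)
})

test_that("semiweak approximation converges to the exact AB spectrum", {
  # the roof tilt reproduces the exact AB intensities; what the first-order
  # (semiweak) construction approximates is the line positions, which must
  # agree within half a grid point for Dv/J >= 4 and degrade monotonically
  # as the coupling gets stronger
  j <- 6
  ax <- test_axis(512)
  grid_hz <- ax$spectral_width / ax$n_points
  ratios <- c(1, 2, 4, 8, 16)
  semiweak_lines <- function(dv) {
    sys <- spin_system(c(3, 3 + dv / 800), matrix(c(0, j, j, 0), 2, 2))
    lines <- do.call(rbind, lapply(1:2, function(i) {
      m <- apply_semiweak_correction(build_multiplet(i, sys), i, sys, 800)
      data.frame(frequency = (sys$shifts[i] - 3) * 800 + m$offset,
                 intensity = m$intensity / 2)
    }))
    lines[order(lines$frequency), ]
  }
  pos_err <- intens_err <- numeric(length(ratios))
  for (k in seq_along(ratios)) {
    dv <- j * ratios[k]
    semi <- semiweak_lines(dv)
    exact <- two_spin_hamiltonian_spectrum(0, dv, j)
    pos_err[k] <- max(abs(semi$frequency - exact$frequency))
    intens_err[k] <- max(abs(semi$intensity - exact$intensity) / exact$intensity)
  }
  expect_lt(pos_err[ratios == 4] / grid_hz, 0.5)
  expect_lt(intens_err[ratios == 4], 0.05)
  expect_true(all(diff(pos_err) < 0))  # strong coupling degrades positions
})
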