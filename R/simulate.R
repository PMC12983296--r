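#' Echo delay schedule
#'
#' The set of spin-echo evolution durations T at which J-modulated spectra are
#' recorded. Chemical-shift evolution is refocused by the echo while scalar
#' couplings evolve for the full duration, so each multiplet component at
#' offset delta from its chemical shift acquires the phase `exp(i*2*pi*delta*T)`
#' and the whole spin is attenuated by `exp(-T/T2)`. The default five delays
#' (0, 10, 30, 50, 90 ms) act as a sparse, exponentially weighted sampling of
#' the J dimension of a J-resolved experiment.
#'
#' @param delays Strictly increasing echo durations in seconds; the first must
#'   be 0 (the conventional spectrum).
#' @return An object of class `echo_schedule`.
#' @export
echo_schedule <- function(delays = c(0, 0.010, 0.030, 0.050, 0.090)) {
  delays <- as.numeric(delays)
  if (length(delays) < 1L || delays[1] != 0)
    stop("first echo delay must be 0")
  if (any(diff(delays) <= 0)) stop("delays must be strictly increasing")
  structure(list(delays = delays), class = "echo_schedule")
}

#' @export
print.echo_schedule <- function(x, ...) {
  cat("<echo_schedule>", paste(x$delays * 1000, collapse = ", "), "ms\n")
  invisible(x)
}

new_spectrum <- function(axis, values) {
  stopifnot(inherits(axis, "spectral_axis"),
            length(values) == axis$n_points, all(is.finite(values)))
  structure(list(axis = axis, values = as.numeric(values)), class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  cat(sprintf("<nmr_spectrum> %d points, max %.4g\n", x$axis$n_points, max(x$values)))
  invisible(x)
}

new_echo_series <- function(schedule, spectra, noise_sigma = NA_real_) {
  stopifnot(inherits(schedule, "echo_schedule"))
  if (length(spectra) != length(schedule$delays))
    stop("number of spectra (", length(spectra), ") must equal number of delays (",
         length(schedule$delays), ")")
  ax <- spectra[[1]]$axis
  for (s in spectra) if (!axes_equal(s$axis, ax)) stop("all spectra must share one axis")
  structure(list(schedule = schedule, spectra = spectra, axis = ax,
                 noise_sigma = noise_sigma),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  cat(sprintf("<echo_series> %d delays (max %g ms), %d points%s\n",
              length(x$schedule$delays), max(x$schedule$delays) * 1000,
              x$axis$n_points,
              if (is.finite(x$noise_sigma)) sprintf(", noise sd %.3g", x$noise_sigma) else ""))
  invisible(x)
}

#' Matrix view of an echo series
#'
#' @param series An echo series.
#' @return `n_points x n_delays` numeric matrix, one column per delay.
#' @export
series_matrix <- function(series) {
  vapply(series$spectra, function(s) s$values, numeric(series$axis$n_points))
}

# Complex Lorentzian FID synthesis shared by the simulator and the target
# builder. Each line l (frequency offset from carrier in Hz, decay rate r2)
# contributes amp[l, r] * exp((2i*pi*f - r2) t) to synthesis row r; the
# time-domain basis of a line is computed once and reused for every row
# (delay). Returns rows of the absorptive real spectrum on the increasing-Hz
# grid (FFT with first point halved, then fftshifted).
synth_spectrum_rows <- function(axis, line_freq, line_r2, amp) {
  n <- axis$n_points
  sw <- axis$spectral_width
  n_rows <- ncol(amp)
  t <- (0:(n - 1L)) / sw
  # basis matrix (time x lines), then all rows in one complex matmul
  B <- exp(t %o% (2i * pi * line_freq - line_r2))
  fid <- B %*% amp
  fid[1L, ] <- fid[1L, ] * 0.5       # half first point: flat baseline offset
  out <- matrix(0, nrow = n, ncol = n_rows)
  half <- n %/% 2L
  for (r in seq_len(n_rows)) {
    sp <- Re(stats::fft(fid[, r]))
    out[, r] <- c(sp[(half + 1L):n], sp[1:half])  # fftshift -> -sw/2 .. +sw/2
  }
  out
}

# Enumerate all multiplet lines of a system (semiweak-tilted unless disabled).
# Returns data.frame(freq offset from carrier Hz, amplitude weight, spin).
system_lines <- function(system, axis, semiweak = TRUE, j_min = 0.2) {
  res <- list()
  for (i in seq_len(n_spins(system))) {
    ml <- build_multiplet(i, system, j_min = j_min)
    if (semiweak)
      ml <- apply_semiweak_correction(ml, i, system, axis$spectrometer_freq)
    f0 <- ppm_to_hz(system$shifts[i], axis)
    res[[i]] <- data.frame(freq = f0 + ml$offset,
                           weight = system$intensities[i] * ml$intensity,
                           delta = ml$offset, spin = i)
  }
  do.call(rbind, res)
}

#' Simulate a spin-echo J-modulated series
#'
#' For every echo delay T, each multiplet component of spin i at offset delta
#' from its chemical shift contributes a complex Lorentzian with amplitude
#' `exp(i*2*pi*delta*T) * exp(-T/t2_i)`: the echo refocuses chemical shift but
#' lets J evolve for the full duration. The stored spectra are the real parts
#' after Fourier transform, with the T = 0 entry phased absorptive (it equals
#' the conventional 1D spectrum). The echo phase factors deliberately leave
#' dispersive character in the T > 0 entries: that is the physical J-modulated
#' lineshape the decoupler consumes.
#'
#' @param system A [spin_system()].
#' @param axis A [spectral_axis()]. Every multiplet line must fall inside the
#'   spectral window, otherwise an aliasing error is raised.
#' @param schedule An [echo_schedule()].
#' @param semiweak Apply the roof-effect intensity tilt
#'   ([apply_semiweak_correction()]) to the multiplet lines? Default TRUE.
#' @param j_min Coupling cutoff (Hz) passed to [build_multiplet()].
#' @param apodization Exponential line broadening (Hz) applied to every
#'   synthesized FID, as in standard NMR processing. The acquisition window is
#'   only `n_points/spectral_width` seconds, so slowly relaxing spins would
#'   otherwise be truncated mid-decay and ring across the spectrum; the
#'   default 3 Hz is matched to the default digital resolution and damps the
#'   FID to ~5% by the end of the window. Applied identically to echo series
#'   and pure-shift targets; it adds to every line's width but leaves total
#'   integrals and the echo-modulation law untouched (the first FID point is
#'   unchanged). Set to 0 for raw truncated lineshapes.
#' @return An `echo_series`.
#' @examples
#' sys <- spin_system(c(2.5, 3.5), matrix(c(0, 8, 8, 0), 2, 2))
#' ser <- simulate_echo_series(sys, spectral_axis(512, 3200, 800, 3))
#' @export
simulate_echo_series <- function(system, axis = spectral_axis(),
                                 schedule = echo_schedule(),
                                 semiweak = TRUE, j_min = 0.2,
                                 apodization = 3) {
  stopifnot(inherits(system, "spin_system"), inherits(axis, "spectral_axis"),
            inherits(schedule, "echo_schedule"))
  if (any(system$t2 <= 0)) stop("all t2 must be positive")
  lines <- system_lines(system, axis, semiweak = semiweak, j_min = j_min)
  lim <- axis$spectral_width / 2
  if (any(abs(lines$freq) >= lim))
    stop(sprintf("multiplet line at %.1f Hz falls outside the spectral window (+/- %.1f Hz): aliasing",
                 lines$freq[which.max(abs(lines$freq))], lim))
  delays <- schedule$delays
  nd <- length(delays)
  # amplitude of line l in delay row r: weight * echo phase * relaxation;
  # apodization broadens the observed line but not the echo decay
  r2 <- 1 / system$t2[lines$spin]
  amp <- lines$weight *
    exp(outer(2i * pi * lines$delta, delays) - outer(r2, delays))
  mat <- synth_spectrum_rows(axis, lines$freq, r2 + pi * apodization, amp)
  spectra <- lapply(seq_len(nd), function(r) new_spectrum(axis, mat[, r]))
  new_echo_series(schedule, spectra)
}

#' Pure-shift training target
#'
#' The spectrum of the same system with every scalar coupling set to zero: one
#' absorptive Lorentzian singlet per spin at its chemical shift, linewidth
#' `1/(pi*t2_i)` plus the apodization broadening, integral proportional to the
#' spin's intensity. Its total integral matches the conventional (T = 0)
#' spectrum of the coupled system to within discretization error.
#'
#' @inheritParams simulate_echo_series
#' @return An `nmr_spectrum`.
#' @export
make_pure_shift_target <- function(system, axis = spectral_axis(),
                                   apodization = 3) {
  stopifnot(inherits(system, "spin_system"), inherits(axis, "spectral_axis"))
  f0 <- ppm_to_hz(system$shifts, axis)
  lim <- axis$spectral_width / 2
  if (any(abs(f0) >= lim))
    stop("chemical shift outside the spectral window")
  amp <- matrix(as.complex(system$intensities), ncol = 1L)
  mat <- synth_spectrum_rows(axis, f0, 1 / system$t2 + pi * apodization, amp)
  new_spectrum(axis, mat[, 1L])
}

#' Add white noise to an echo series
#'
#' Independent Gaussian noise is added to every point of every spectrum. The
#' signal-to-noise ratio is defined against the tallest peak of the (noiseless)
#' T = 0 spectrum: `sigma = max(T0) / snr`. The realized `noise_sigma` is
#' recorded on the series. Reproducible for a fixed seed.
#'
#' @param series An `echo_series` (assumed noiseless for the SNR definition).
#' @param snr Target signal-to-noise ratio (> 0).
#' @param seed Integer seed.
#' @return A new `echo_series` with noisy spectra and `noise_sigma` set.
#' @export
add_noise <- function(series, snr, seed) {
  stopifnot(inherits(series, "echo_series"))
  if (!is.finite(snr) || snr <= 0) stop("snr must be positive")
  sigma <- max(series$spectra[[1]]$values) / snr
  n <- series$axis$n_points
  spectra <- with_seed(seed, {
    lapply(series$spectra, function(s)
      new_spectrum(s$axis, s$values + stats::rnorm(n, sd = sigma)))
  })
  new_echo_series(series$schedule, spectra, noise_sigma = sigma)
}

#' Integral of a spectrum
#'
#' Riemann sum over the full grid, in intensity times Hz (or ppm).
#'
#' @param spectrum An `nmr_spectrum`.
#' @param units `"hz"` or `"ppm"` step width.
#' @return Numeric scalar.
#' @export
spectrum_integral <- function(spectrum, units = c("hz", "ppm")) {
  units <- match.arg(units)
  ax <- spectrum$axis
  step <- ax$spectral_width / ax$n_points
  if (units == "ppm") step <- step / ax$spectrometer_freq
  sum(spectrum$values) * step
}
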