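#' Spectral axis
#'
#' Defines the frequency grid on which spectra are simulated and processed.
#' Internally the grid is indexed by strictly increasing frequency offset from
#' the carrier (Hz); point `k` (1-based) sits at
#' `-sw/2 + (k-1) * sw/n` Hz, i.e. ppm increases with index. Display
#' conventions (ppm decreasing left to right) are left to the caller;
#' [axis_ppm()] and [axis_hz()] give the grid in either unit.
#'
#' @param n_points Number of grid points; must be a power of two, at least 64.
#' @param spectral_width Spectral width in Hz (> 0).
#' @param spectrometer_freq Spectrometer (proton Larmor) frequency in MHz.
#' @param center_shift Chemical shift (ppm) of the carrier / window centre.
#' @return An object of class `spectral_axis`.
#' @examples
#' ax <- spectral_axis(2048, 3200, 800, 3)
#' range(axis_ppm(ax))
#' @export
spectral_axis <- function(n_points = 2048, spectral_width = 3200,
                          spectrometer_freq = 800, center_shift = 3) {
  n_points <- as.integer(n_points)
  if (n_points < 64L || bitwAnd(n_points, n_points - 1L) != 0L)
    stop("n_points must be a power of two and at least 64, got ", n_points)
  if (!is.finite(spectral_width) || spectral_width <= 0)
    stop("spectral_width must be positive")
  if (!is.finite(spectrometer_freq) || spectrometer_freq <= 0)
    stop("spectrometer_freq must be positive")
  structure(
    list(n_points = n_points, spectral_width = spectral_width,
         spectrometer_freq = spectrometer_freq, center_shift = center_shift),
    class = "spectral_axis")
}

#' @rdname spectral_axis
#' @param axis A `spectral_axis`.
#' @return `axis_hz()`: frequency offsets from the carrier (Hz), increasing.
#' @export
axis_hz <- function(axis) {
  stopifnot(inherits(axis, "spectral_axis"))
  n <- axis$n_points
  -axis$spectral_width / 2 + (0:(n - 1L)) * axis$spectral_width / n
}

#' @rdname spectral_axis
#' @return `axis_ppm()`: chemical shifts (ppm) of the grid, increasing.
#' @export
axis_ppm <- function(axis) {
  axis$center_shift + axis_hz(axis) / axis$spectrometer_freq
}

#' Convert between ppm and Hz offsets on an axis
#'
#' Offsets are measured from the carrier: `Hz = (ppm - center) * MHz`.
#'
#' @param ppm,hz Values to convert.
#' @param axis A [spectral_axis()].
#' @return Converted numeric vector.
#' @export
ppm_to_hz <- function(ppm, axis) (ppm - axis$center_shift) * axis$spectrometer_freq

#' @rdname ppm_to_hz
#' @export
hz_to_ppm <- function(hz, axis) axis$center_shift + hz / axis$spectrometer_freq

#' @export
print.spectral_axis <- function(x, ...) {
  cat(sprintf("<spectral_axis> %d points, %.1f Hz (%.3f ppm) at %.1f MHz, centre %.3f ppm\n",
              x$n_points, x$spectral_width,
              x$spectral_width / x$spectrometer_freq,
              x$spectrometer_freq, x$center_shift))
  invisible(x)
}

axes_equal <- function(a, b, tol = 1e-9) {
  a$n_points == b$n_points &&
    abs(a$spectral_width - b$spectral_width) < tol &&
    abs(a$spectrometer_freq - b$spectrometer_freq) < tol &&
    abs(a$center_shift - b$center_shift) < tol
}
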