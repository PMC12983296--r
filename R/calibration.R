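#' Estimate the signal-to-noise ratio of an echo series
#'
#' If the series carries a recorded `noise_sigma` (e.g. from [add_noise()]),
#' the ratio `max(T0)/noise_sigma` is returned directly. Otherwise the noise
#' floor is estimated robustly from the high-frequency content of the T = 0
#' spectrum: `1.4826 x MAD(second differences) / sqrt(6)`, which recovers the
#' standard deviation of white noise exactly (the second difference of i.i.d.
#' noise has variance `6 sigma^2`) while annihilating the smooth signal
#' structure — Lorentzian tails and baseline roll are locally linear, so they
#' would inflate a floor estimated from raw intensities but vanish from the
#' curvature; the median absolute deviation makes the sparse sharp peaks
#' irrelevant. The estimate is capped at 1e9 for (near-)noiseless data.
#'
#' @param series An `echo_series` with at least one spectrum.
#' @return SNR (dimensionless), in (0, 1e9].
#' @export
estimate_snr <- function(series) {
  stopifnot(inherits(series, "echo_series"), length(series$spectra) >= 1L)
  v <- series$spectra[[1L]]$values
  peak <- max(v)
  if (all(v == 0)) stop("all-zero spectrum: SNR undefined")
  if (is.finite(series$noise_sigma) && !is.na(series$noise_sigma) &&
      series$noise_sigma > 0)
    return(min(peak / series$noise_sigma, 1e9))
  noise <- 1.4826 * stats::mad(diff(v, differences = 2), constant = 1) / sqrt(6)
  if (noise <= 0) return(1e9)
  min(peak / noise, 1e9)
}

new_calibration_curve <- function(snr_grid, factors, valid_range = c(20, 1e5),
                                  model_version = NA_character_) {
  stopifnot(length(snr_grid) == length(factors), length(snr_grid) >= 2L,
            all(diff(snr_grid) > 0), all(factors > 0))
  structure(list(snr_grid = as.numeric(snr_grid),
                 correction_factor = as.numeric(factors),
                 valid_range = as.numeric(valid_range),
                 model_version = model_version),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %d grid SNRs in [%g, %g], factors %.2f-%.2f\n",
              length(x$snr_grid), x$valid_range[1], x$valid_range[2],
              min(x$correction_factor), max(x$correction_factor)))
  invisible(x)
}

#' Build the SNR-dependent uncertainty calibration curve
#'
#' Networks trained across a wide noise range tend to mis-scale their
#' predicted uncertainties. For each grid SNR this simulates `n_reps` fresh
#' systems, decouples them and computes the multiplicative correction
#' `factor = RMS(residual vs true target) / RMS(predicted sigma)`: the factor
#' is 1 exactly when the predicted sigmas carry the energy of the true
#' residuals (a model whose sigma is uniformly halved gets factor 2). RMS is
#' used on both sides — dividing by the *mean* sigma would leave the factor
#' above 1 even for a perfectly calibrated heteroscedastic model (Jensen gap
#' between RMS and mean over a sigma field that spans orders of magnitude
#' from baseline to peaks) and systematically over-inflate the corrected
#' uncertainties. Queries between grid points interpolate linearly in
#' log(SNR); queries outside the validity range are clamped to the nearest
#' edge with a warning.
#'
#' @param model Trained `decoupler_model`.
#' @param snr_grid Ascending SNR grid; default 8 log-spaced points over the
#'   validity span 20 to 1e5.
#' @param n_reps Systems simulated per grid point (>= 2).
#' @param seed Integer seed.
#' @param gen_config,axis,schedule Synthetic distribution and grid.
#' @param valid_range Validity span recorded on the curve.
#' @return A `calibration_curve`.
#' @export
calibrate_uncertainties <- function(model,
                                    snr_grid = exp(seq(log(20), log(1e5), length.out = 8)),
                                    n_reps = 8L, seed = 1L,
                                    gen_config = spin_gen_config(),
                                    axis = spectral_axis(1024),
                                    schedule = echo_schedule(),
                                    valid_range = c(20, 1e5)) {
  stopifnot(inherits(model, "decoupler_model"))
  if (n_reps < 2L) stop("n_reps must be at least 2")
  if (any(diff(snr_grid) <= 0)) stop("snr_grid must be ascending")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max,
                                      2L * n_reps * length(snr_grid)))
  factors <- numeric(length(snr_grid))
  k <- 0L
  for (g in seq_along(snr_grid)) {
    ss_res <- 0; s_sig <- 0; npts <- 0
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      sys <- random_spin_system(seeds[2L * k - 1L], gen_config)
      ser <- suppressWarnings(simulate_echo_series(sys, axis, schedule))
      noisy <- add_noise(ser, snr_grid[g], seeds[2L * k])
      res <- decouple(model, noisy)
      tgt <- make_pure_shift_target(sys, axis)
      ss_res <- ss_res + sum((res$intensity - tgt$values)^2)
      s_sig <- s_sig + sum(res$sigma^2)
      npts <- npts + axis$n_points
    }
    factors[g] <- sqrt(ss_res / npts) / sqrt(s_sig / npts)
  }
  new_calibration_curve(snr_grid, factors, valid_range, model$version)
}

#' Interpolate a calibration factor at an SNR
#'
#' @param curve A `calibration_curve`.
#' @param snr Query SNR.
#' @return Multiplicative sigma correction factor.
#' @export
calibration_factor <- function(curve, snr) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (snr < curve$valid_range[1] || snr > curve$valid_range[2]) {
    warning(sprintf("SNR %.3g outside calibration validity range [%g, %g]; using nearest edge",
                    snr, curve$valid_range[1], curve$valid_range[2]))
    snr <- min(max(snr, curve$snr_grid[1]), curve$snr_grid[length(curve$snr_grid)])
  }
  snr <- min(max(snr, curve$snr_grid[1]), curve$snr_grid[length(curve$snr_grid)])
  stats::approx(log(curve$snr_grid), curve$correction_factor, xout = log(snr))$y
}

#' Apply the calibration curve to a decoupling result
#'
#' Multiplies the predicted sigma by the factor interpolated at `snr`; the
#' intensity trace is untouched. A result may only be calibrated once.
#'
#' @param result An uncalibrated `pure_shift_result`.
#' @param curve A `calibration_curve`.
#' @param snr SNR of the input series (see [estimate_snr()]).
#' @return The calibrated `pure_shift_result`.
#' @export
apply_calibration <- function(result, curve, snr) {
  stopifnot(inherits(result, "pure_shift_result"))
  if (isTRUE(result$calibrated)) stop("result is already calibrated")
  f <- calibration_factor(curve, snr)
  result$sigma <- result$sigma * f
  result$calibrated <- TRUE
  result
}

#' Empirical 1-sigma coverage of predicted uncertainties
#'
#' Fraction of points whose true value lies within one predicted sigma of the
#' predicted intensity; about 0.683 for well-calibrated Gaussian errors.
#'
#' @param results List of `pure_shift_result` (or a single one).
#' @param truths Matching list of `nmr_spectrum` ground truths.
#' @param bins Optional factor/vector (one per result) to additionally report
#'   coverage by group, e.g. SNR bins.
#' @return Overall coverage fraction; if `bins` is given, attribute
#'   `by_bin` holds a per-group data frame.
#' @export
coverage_check <- function(results, truths, bins = NULL) {
  if (inherits(results, "pure_shift_result")) results <- list(results)
  if (inherits(truths, "nmr_spectrum")) truths <- list(truths)
  if (length(results) != length(truths)) stop("mismatched result/truth lengths")
  hit <- function(r, t) {
    if (!axes_equal(r$axis, t$axis)) stop("mismatched axes")
    abs(r$intensity - t$values) <= r$sigma
  }
  hits <- Map(hit, results, truths)
  overall <- mean(unlist(hits))
  if (!is.null(bins)) {
    stopifnot(length(bins) == length(results))
    per <- vapply(split(hits, bins), function(h) mean(unlist(h)), numeric(1))
    attr(overall, "by_bin") <- data.frame(bin = names(per), coverage = as.numeric(per))
  }
  overall
}

#' Serialize / read a calibration curve (JSON)
#'
#' @param curve A `calibration_curve`.
#' @param path File path.
#' @return `read_calibration()` returns the curve.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  jsonlite::write_json(
    list(format = "pureshiftnn-calibration", model_version = curve$model_version,
         snr_grid = curve$snr_grid, correction_factor = curve$correction_factor,
         valid_range = curve$valid_range),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "pureshiftnn-calibration"))
    stop("not a calibration curve file: ", path)
  new_calibration_curve(obj$snr_grid, obj$correction_factor, obj$valid_range,
                        obj$model_version)
}
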