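#' Peak regions
#'
#' Labelled integration regions in ppm.
#'
#' @param label Character labels.
#' @param low,high Region bounds in ppm (`low < high`).
#' @return A data frame of class `peak_regions`.
#' @export
peak_regions <- function(label, low, high) {
  stopifnot(length(label) == length(low), length(low) == length(high))
  if (any(low >= high)) stop("every region needs low < high")
  structure(data.frame(label = as.character(label), low = low, high = high),
            class = c("peak_regions", "data.frame"))
}

#' Read a three-column regions file
#'
#' Whitespace-separated text: `label low_ppm high_ppm`, one region per line;
#' lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return A [peak_regions()] table.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, header = FALSE, comment.char = "#",
                          col.names = c("label", "low", "high"),
                          colClasses = c("character", "numeric", "numeric"))
  peak_regions(df$label, df$low, df$high)
}

#' Integrate peaks with propagated uncertainties
#'
#' Trapezoidal integral of the decoupled trace over each region, with the
#' per-point predicted uncertainties propagated as independent errors:
#' `integral_sigma = sqrt(sum(sigma_p^2)) * dppm`. Warns if the result has not
#' been calibrated and if regions overlap.
#'
#' @param result A `pure_shift_result`.
#' @param regions A [peak_regions()] table.
#' @return Data frame `label, integral, integral_sigma` (intensity x ppm).
#' @export
integrate_peaks <- function(result, regions) {
  stopifnot(inherits(result, "pure_shift_result"))
  if (!isTRUE(result$calibrated))
    warning("result is not calibrated; integral uncertainties are raw model sigmas")
  ppm <- axis_ppm(result$axis)
  dppm <- result$axis$spectral_width / result$axis$n_points /
    result$axis$spectrometer_freq
  nr <- nrow(regions)
  if (nr >= 2L) {
    ov <- FALSE
    for (i in 1:(nr - 1L)) for (j in (i + 1L):nr)
      if (regions$low[i] < regions$high[j] && regions$low[j] < regions$high[i])
        ov <- TRUE
    if (ov) warning("some integration regions overlap")
  }
  out <- regions
  out$integral <- NA_real_; out$integral_sigma <- NA_real_
  for (i in seq_len(nr)) {
    idx <- which(ppm >= regions$low[i] & ppm <= regions$high[i])
    if (length(idx) == 0L)
      stop("region '", regions$label[i], "' contains no grid points")
    v <- result$intensity[idx]
    w <- rep(1, length(v)); w[1] <- w[length(v)] <- 0.5  # trapezoid
    out$integral[i] <- sum(v * w) * dppm
    out$integral_sigma[i] <- sqrt(sum(result$sigma[idx]^2)) * dppm
  }
  as.data.frame(out)[, c("label", "integral", "integral_sigma")]
}

#' Pearson correlation between integrals and concentrations
#'
#' Standard product-moment correlation, requiring at least 3 points and
#' nonzero variance on both sides.
#'
#' @param integrals,concentrations Numeric vectors of equal length.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_r <- function(integrals, concentrations) {
  if (length(integrals) != length(concentrations)) stop("length mismatch")
  if (length(integrals) < 3L) stop("need at least 3 points")
  if (stats::sd(integrals) == 0 || stats::sd(concentrations) == 0)
    stop("constant input: correlation undefined")
  stats::cor(integrals, concentrations)
}

#' Time-normalized RMSD of a quantification line
#'
#' Fits `integral ~ concentration` by least squares and reports
#' `rho_tilde = f(t_acq / t_acq_conv) * RMSD(residuals) / slope`, a
#' dimensionless figure of how tightly integrals track concentration once the
#' extra measurement time of the echo series (five spectra vs one conventional
#' spectrum) is accounted for. The default time factor is
#' `sqrt(t_acq/t_acq_conv)` (sensitivity scales with the square root of
#' measurement time); set `time_power = "linear"` for a linear factor.
#'
#' @param integrals,concentrations Numeric vectors (>= 3 points).
#' @param t_acq Acquisition time of the evaluated experiment (s).
#' @param t_acq_conv Acquisition time of the conventional reference (s).
#' @param time_power `"sqrt"` (default) or `"linear"`.
#' @return `rho_tilde` (dimensionless, >= 0).
#' @export
normalized_rmsd <- function(integrals, concentrations, t_acq, t_acq_conv,
                            time_power = c("sqrt", "linear")) {
  time_power <- match.arg(time_power)
  if (length(integrals) != length(concentrations)) stop("length mismatch")
  if (length(integrals) < 3L) stop("need at least 3 points")
  if (t_acq <= 0 || t_acq_conv <= 0) stop("acquisition times must be positive")
  fit <- stats::lm(integrals ~ concentrations)
  slope <- stats::coef(fit)[["concentrations"]]
  if (is.na(slope) || slope == 0) stop("zero or singular slope: rho_tilde undefined")
  rmsd <- sqrt(mean(stats::residuals(fit)^2))
  tf <- t_acq / t_acq_conv
  if (time_power == "sqrt") tf <- sqrt(tf)
  tf * rmsd / abs(slope)
}

#' Noise-titration sensitivity evaluation
#'
#' Adds white noise to a reference echo series at each of several descending
#' SNR levels, decouples and calibrates each, and reports for every region
#' whether its peak is retained: maximum intensity in the region at least
#' `3 x` the local uncertainty (median sigma within the region). Averaging
#' over seeds gives a retention-vs-noise profile, which for a working
#' decoupler is non-increasing as noise grows.
#'
#' @param series A noiseless `echo_series`.
#' @param snr_levels Descending SNR levels.
#' @param model Trained `decoupler_model`.
#' @param curve A `calibration_curve`.
#' @param regions A [peak_regions()] table.
#' @param seed Integer seed.
#' @return Data frame `snr, label, retained` plus a `retention` attribute:
#'   the retained fraction per SNR level (in input order).
#' @export
noise_titration <- function(series, snr_levels, model, curve, regions, seed = 1L) {
  if (any(diff(snr_levels) >= 0)) stop("snr_levels must be descending")
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, length(snr_levels)))
  ppm <- axis_ppm(series$axis)
  rows <- list()
  for (li in seq_along(snr_levels)) {
    noisy <- add_noise(series, snr_levels[li], seeds[li])
    res <- decouple(model, noisy)
    res <- suppressWarnings(apply_calibration(res, curve, estimate_snr(noisy)))
    for (i in seq_len(nrow(regions))) {
      idx <- which(ppm >= regions$low[i] & ppm <= regions$high[i])
      retained <- max(res$intensity[idx]) >= 3 * stats::median(res$sigma[idx])
      rows[[length(rows) + 1L]] <- data.frame(
        snr = snr_levels[li], label = regions$label[i], retained = retained)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "retention") <- vapply(snr_levels, function(s)
    mean(out$retained[out$snr == s]), numeric(1))
  out
}

#' Flag uncertainty spikes
#'
#' A sudden localized spike of the predicted uncertainty marks a resonance
#' that may be an artifact of the transform. Points whose sigma exceeds
#' `z x` the rolling-median sigma (window of `window` points) are flagged.
#'
#' @param result A calibrated `pure_shift_result`.
#' @param z Spike threshold in multiples of the local median (default 5).
#' @param window Rolling-median window length in points (odd; default 51).
#' @return Data frame `index, ppm, sigma, ratio` of flagged points (possibly
#'   empty).
#' @export
flag_uncertainty_spikes <- function(result, z = 5, window = 51L) {
  stopifnot(inherits(result, "pure_shift_result"))
  if (window %% 2L == 0L) stop("window must be odd")
  med <- stats::runmed(result$sigma, window, endrule = "median")
  ratio <- result$sigma / med
  idx <- which(ratio > z)
  data.frame(index = idx, ppm = axis_ppm(result$axis)[idx],
             sigma = result$sigma[idx], ratio = ratio[idx])
}
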