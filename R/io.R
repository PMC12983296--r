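#' Write / read an echo series as a columnar text file
#'
#' The container is a plain-text file: a header of `# key: value` lines with
#' the stable keys `n_points`, `spectral_width_hz`, `spectrometer_freq_mhz`,
#' `center_ppm`, `delays_s` (comma-separated, seconds) and `noise_sigma`
#' (`NA` if unknown), followed by one whitespace-separated row per grid point
#' with one intensity column per delay. Values are written with 17 significant
#' digits, so a write/read round trip is exact at float64.
#'
#' @param series An `echo_series`.
#' @param path File path.
#' @return `read_echo_series()` returns the `echo_series`.
#' @export
write_echo_series <- function(series, path) {
  stopifnot(inherits(series, "echo_series"))
  ax <- series$axis
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  writeLines(c(
    "# pureshiftnn echo-series v1",
    paste0("# n_points: ", ax$n_points),
    paste0("# spectral_width_hz: ", num(ax$spectral_width)),
    paste0("# spectrometer_freq_mhz: ", num(ax$spectrometer_freq)),
    paste0("# center_ppm: ", num(ax$center_shift)),
    paste0("# delays_s: ", paste(num(series$schedule$delays), collapse = ",")),
    paste0("# noise_sigma: ",
           if (is.na(series$noise_sigma)) "NA" else num(series$noise_sigma))
  ), con)
  m <- series_matrix(series)
  chm <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  utils::write.table(chm, con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

parse_header <- function(lines) {
  hdr <- grep("^#", lines, value = TRUE)
  out <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([a-z_]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) out[[m[2]]] <- m[3]
  }
  out
}

#' @rdname write_echo_series
#' @export
read_echo_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- parse_header(lines)
  need <- c("n_points", "spectral_width_hz", "spectrometer_freq_mhz",
            "center_ppm", "delays_s")
  missing <- setdiff(need, names(hdr))
  if (length(missing))
    stop("malformed echo-series header: missing ", paste(missing, collapse = ", "))
  ax <- spectral_axis(as.integer(hdr$n_points),
                      as.numeric(hdr$spectral_width_hz),
                      as.numeric(hdr$spectrometer_freq_mhz),
                      as.numeric(hdr$center_ppm))
  delays <- as.numeric(strsplit(hdr$delays_s, ",")[[1]])
  noise_sigma <- if (is.null(hdr$noise_sigma) || hdr$noise_sigma == "NA")
    NA_real_ else as.numeric(hdr$noise_sigma)
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"),
                             function(x) as.numeric(x)))
  if (nrow(m) != ax$n_points)
    stop("echo-series body has ", nrow(m), " rows but header says n_points = ",
         ax$n_points)
  if (ncol(m) != length(delays))
    stop("file has ", ncol(m), " intensity columns but ", length(delays),
         " delays in the header")
  spectra <- lapply(seq_len(ncol(m)), function(j) new_spectrum(ax, m[, j]))
  new_echo_series(echo_schedule(delays), spectra, noise_sigma)
}

#' Write / read a pure-shift result as a columnar text file
#'
#' Same header convention as [write_echo_series()] (plus a `calibrated` flag);
#' the body holds two columns, intensity and sigma.
#'
#' @param result A `pure_shift_result`.
#' @param path File path.
#' @return `read_pure_shift_result()` returns the result.
#' @export
write_pure_shift_result <- function(result, path) {
  stopifnot(inherits(result, "pure_shift_result"))
  ax <- result$axis
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) sprintf("%.17g", x)
  writeLines(c(
    "# pureshiftnn pure-shift-result v1",
    paste0("# n_points: ", ax$n_points),
    paste0("# spectral_width_hz: ", num(ax$spectral_width)),
    paste0("# spectrometer_freq_mhz: ", num(ax$spectrometer_freq)),
    paste0("# center_ppm: ", num(ax$center_shift)),
    paste0("# calibrated: ", if (isTRUE(result$calibrated)) "true" else "false")
  ), con)
  utils::write.table(cbind(sprintf("%.17g", result$intensity),
                           sprintf("%.17g", result$sigma)),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_pure_shift_result
#' @export
read_pure_shift_result <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  hdr <- parse_header(lines)
  ax <- spectral_axis(as.integer(hdr$n_points),
                      as.numeric(hdr$spectral_width_hz),
                      as.numeric(hdr$spectrometer_freq_mhz),
                      as.numeric(hdr$center_ppm))
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  m <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), as.numeric))
  new_pure_shift_result(ax, m[, 1], m[, 2],
                        calibrated = identical(hdr$calibrated, "true"))
}

#' Read a Bruker processed 1D spectrum
#'
#' Reads a TopSpin processed-data directory (a `procno` directory containing
#' the real processed vector `1r` and the parameter file `procs`). The `1r`
#' file holds 32-bit integers scaled by `2^NC_proc`; byte order follows
#' `BYTORDP`. The frequency axis is reconstructed from `SI` (points), `SW_p`
#' (spectral width, Hz), `SF` (spectrometer frequency, MHz) and `OFFSET` (ppm
#' of the left, high-frequency edge). Bruker stores points from high to low
#' ppm; they are reversed onto this package's increasing-frequency grid.
#'
#' @param path Directory containing `1r` and `procs`.
#' @return An `nmr_spectrum`.
#' @export
read_bruker_1d <- function(path) {
  f1r <- file.path(path, "1r")
  fpr <- file.path(path, "procs")
  if (!file.exists(fpr)) stop("missing parameter file: ", fpr)
  if (!file.exists(f1r)) stop("missing data file: ", f1r)
  txt <- readLines(fpr, warn = FALSE)
  getpar <- function(name) {
    ln <- grep(paste0("^##\\$", name, "="), txt, value = TRUE)
    if (length(ln) == 0L) stop("procs is missing parameter ", name)
    as.numeric(sub(paste0("^##\\$", name, "=\\s*"), "", ln[1]))
  }
  si <- as.integer(getpar("SI"))
  swp <- getpar("SW_p")
  sf <- getpar("SF")
  offset <- getpar("OFFSET")
  byto <- getpar("BYTORDP")
  ncproc <- getpar("NC_proc")
  endian <- if (byto == 0) "little" else "big"
  raw <- readBin(f1r, what = "integer", n = si + 1L, size = 4L, endian = endian)
  if (length(raw) < si)
    stop("truncated 1r file: expected ", si, " points, got ", length(raw))
  values <- raw[seq_len(si)] * 2^ncproc
  # Bruker stores point k (0-based) at OFFSET - k*SW_p/(SF*SI) ppm; choose the
  # window centre so our increasing grid's last point lands exactly at OFFSET
  center <- offset - swp / (2 * sf) + swp / (sf * si)
  ax <- spectral_axis(si, swp, sf, center)
  new_spectrum(ax, rev(values))
}
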