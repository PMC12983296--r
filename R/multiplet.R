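#' First-order multiplet of a spin
#'
#' Builds the weak-coupling multiplet of one spin: each coupling partner j in
#' spin state m_j = +/- 1/2 shifts the resonance by `m_j * J_ij`, so the line
#' offsets are all sums over partners and the intensities follow the binomial
#' pattern (1:2:1 for two equivalent partners, and so on). Couplings with
#' `|J| <= j_min` are ignored to bound the tree. Lines degenerate within
#' 1e-9 Hz are merged by summing intensities.
#'
#' The returned data frame carries the per-line partner spin states as
#' attributes (`mstates`, a lines x partners matrix of +/- 1/2, and
#' `partners`, the partner indices) so that [apply_semiweak_correction()] can
#' tilt intensities per partner; merging only combines lines whose tilt would
#' be identical.
#'
#' @param spin_index Index of the spin (1-based).
#' @param system A [spin_system()].
#' @param j_min Couplings with `|J|` at or below this cutoff (Hz) are dropped.
#' @return `data.frame(offset, intensity)`: offsets in Hz from the spin's
#'   chemical shift; intensities sum to 1.
#' @examples
#' sys <- spin_system(c(2, 3, 4), matrix(c(0, 7, 7, 7, 0, 0, 7, 0, 0), 3, 3))
#' build_multiplet(1, sys)   # 1:2:1 triplet
#' @export
build_multiplet <- function(spin_index, system, j_min = 0.2) {
  stopifnot(inherits(system, "spin_system"))
  n <- n_spins(system)
  if (length(spin_index) != 1L || spin_index < 1L || spin_index > n)
    stop("spin_index out of range [1, ", n, "]")
  if (max(abs(system$couplings - t(system$couplings))) > 1e-9)
    stop("coupling matrix is not symmetric")
  js <- system$couplings[spin_index, ]
  partners <- setdiff(which(abs(js) > j_min), spin_index)
  offsets <- 0
  mstates <- matrix(numeric(0), nrow = 1L, ncol = 0L)
  for (p in partners) {
    offsets <- c(offsets - js[p] / 2, offsets + js[p] / 2)
    mstates <- rbind(cbind(mstates, -0.5), cbind(mstates, +0.5))
  }
  k <- length(offsets)
  raw <- list(offset = offsets, intensity = rep(1 / k, k),
              mstates = mstates, partners = partners)
  out <- merge_degenerate_lines(raw$offset, raw$intensity)
  attr(out, "raw") <- raw
  attr(out, "mstates") <- mstates
  attr(out, "partners") <- partners
  out
}

# Merge lines whose offsets coincide within `tol` Hz by summing intensities.
merge_degenerate_lines <- function(offset, intensity, tol = 1e-9) {
  ord <- order(offset)
  o <- offset[ord]; inten <- intensity[ord]
  keep_o <- numeric(0); keep_i <- numeric(0)
  i <- 1L
  while (i <= length(o)) {
    j <- i
    while (j < length(o) && o[j + 1L] - o[i] <= tol) j <- j + 1L
    keep_o <- c(keep_o, o[i])
    keep_i <- c(keep_i, sum(inten[i:j]))
    i <- j + 1L
  }
  data.frame(offset = keep_o, intensity = keep_i)
}

#' Semiweak (roof-effect) intensity correction
#'
#' Tilts first-order multiplet intensities by the AB roof effect: for each
#' coupling partner j, with shift difference `dnu` (Hz) and
#' `D = sqrt(dnu^2 + J^2)`, the line on the side facing the partner is
#' enhanced by `1 + |J|/D` and the outer line reduced by `1 - |J|/D`. Line
#' positions are left at their first-order values, so this is a semiweak
#' approximation: it captures the leading intensity distortion of moderately
#' strong coupling but not the frequency shifts of a full AB treatment. In the
#' weak-coupling limit (`|dnu| >> |J|`) the correction tends to the identity.
#' Total intensity is conserved exactly (pairwise factors sum to 2).
#'
#' A degenerate, magnetically inequivalent pair (`dnu == 0` with `J != 0`)
#' is genuinely strongly coupled; for such partners the correction is skipped
#' and a warning is recorded (also available as the `strong_coupled`
#' attribute of the result).
#'
#' @param lines Output of [build_multiplet()] for the same spin (the partner
#'   spin-state bookkeeping it carries is required; the tilt is applied to the
#'   unmerged line tree and degenerate lines re-merged afterwards, which keeps
#'   the total intensity conserved exactly).
#' @param spin_index Index of the spin the multiplet belongs to.
#' @param system The [spin_system()].
#' @param spectrometer_freq Spectrometer frequency (MHz), used to convert ppm
#'   shift differences to Hz.
#' @return The lines with tilted intensities (same container and attributes);
#'   attribute `strong_coupled` lists partner indices that were skipped.
#' @export
apply_semiweak_correction <- function(lines, spin_index, system,
                                      spectrometer_freq = 800) {
  raw <- attr(lines, "raw")
  if (is.null(raw))
    stop("lines must come from build_multiplet() (partner state bookkeeping missing)")
  partners <- raw$partners
  if (length(partners) == 0L) return(lines)
  ms <- raw$mstates
  inten <- raw$intensity
  skipped <- integer(0)
  for (k in seq_along(partners)) {
    p <- partners[k]
    jsig <- system$couplings[spin_index, p]
    jab <- abs(jsig)
    dnu <- (system$shifts[spin_index] - system$shifts[p]) * spectrometer_freq
    if (abs(dnu) < 1e-9) {
      skipped <- c(skipped, p)
      next
    }
    d <- sqrt(dnu^2 + jab^2)
    # inner line = the component displaced toward the partner
    inner <- sign(ms[, k] * jsig) == -sign(dnu)
    inten <- inten * ifelse(inner, 1 + jab / d, 1 - jab / d)
  }
  if (length(skipped))
    warning(sprintf("spin %d: strongly coupled degenerate partner(s) %s; roof correction skipped",
                    spin_index, paste(skipped, collapse = ", ")))
  out <- merge_degenerate_lines(raw$offset, inten)
  raw$intensity <- inten
  attr(out, "raw") <- raw
  attr(out, "mstates") <- attr(lines, "mstates")
  attr(out, "partners") <- partners
  attr(out, "strong_coupled") <- skipped
  out
}

#' Exact two-spin (AB) stick spectrum
#'
#' Closed-form transition frequencies and intensities of a coupled two-spin
#' system, valid at any coupling strength. With `dnu = shift_a - shift_b` and
#' `D = sqrt(dnu^2 + J^2)` the four lines sit at `center +/- (D +/- |J|)/2`;
#' the outer pair has intensity proportional to `1 - |J|/D` and the inner pair
#' to `1 + |J|/D` (the roof effect). Serves as the exact oracle for the
#' strong-coupling regime that the semiweak training approximation does not
#' model.
#'
#' @param shift_a,shift_b Resonance frequencies of the two spins (Hz).
#' @param j Scalar coupling (Hz).
#' @return `data.frame(frequency, intensity)` with intensities summing to 1.
#'   Degenerate lines are merged (uncoupled limit: two lines; equivalent A2
#'   limit: a single line).
#' @examples
#' exact_two_spin_spectrum(5, -5, 6)
#' @export
exact_two_spin_spectrum <- function(shift_a, shift_b, j) {
  center <- (shift_a + shift_b) / 2
  dnu <- shift_a - shift_b
  jab <- abs(j)
  if (dnu == 0) {            # A2: coupling between equivalent spins invisible
    return(data.frame(frequency = center, intensity = 1))
  }
  if (jab == 0) {
    return(data.frame(frequency = sort(c(shift_a, shift_b)),
                      intensity = c(0.5, 0.5)))
  }
  d <- sqrt(dnu^2 + jab^2)
  freq <- center + c(-(d + jab) / 2, -(d - jab) / 2, (d - jab) / 2, (d + jab) / 2)
  inten <- c(1 - jab / d, 1 + jab / d, 1 + jab / d, 1 - jab / d)
  df <- data.frame(frequency = freq, intensity = inten / sum(inten))
  df <- df[order(df$frequency), ]
  rownames(df) <- NULL
  df
}
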