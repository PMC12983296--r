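#' Spin system
#'
#' A weakly/semiweakly coupled proton spin system: chemical shifts (ppm), a
#' symmetric scalar-coupling matrix (Hz, zero diagonal), per-spin relative
#' intensities (populations) and transverse relaxation times T2 (s). T2 sets
#' the Lorentzian linewidth `1/(pi*T2)` and the amplitude decay
#' `exp(-T/T2)` across spin-echo delays.
#'
#' @param shifts Numeric vector of chemical shifts (ppm), one per spin.
#' @param couplings Symmetric numeric matrix of scalar couplings J (Hz), zero
#'   diagonal. A scalar 0 is accepted for uncoupled systems.
#' @param intensities Relative intensity (population) per spin, all > 0.
#'   Default 1 for every spin.
#' @param t2 Transverse relaxation time (s) per spin, all > 0. Recycled if
#'   length 1. Default 1 s.
#' @return An object of class `spin_system`.
#' @examples
#' # an AX doublet pair: 7 Hz coupling
#' sys <- spin_system(c(2.0, 4.0), matrix(c(0, 7, 7, 0), 2, 2))
#' @export
spin_system <- function(shifts, couplings = NULL, intensities = NULL, t2 = NULL) {
  n <- length(shifts)
  if (n < 1L) stop("need at least one spin")
  if (is.null(couplings)) couplings <- matrix(0, n, n)
  if (length(couplings) == 1L && n > 1L) couplings <- matrix(0, n, n)
  couplings <- as.matrix(couplings)
  if (!all(dim(couplings) == c(n, n)))
    stop("couplings must be an n x n matrix (n = ", n, ")")
  if (max(abs(couplings - t(couplings))) > 1e-9)
    stop("couplings matrix must be symmetric")
  if (any(diag(couplings) != 0))
    stop("couplings matrix must have zero diagonal")
  if (is.null(intensities)) intensities <- rep(1, n)
  if (is.null(t2)) t2 <- rep(1, n)
  if (length(t2) == 1L) t2 <- rep(t2, n)
  if (length(intensities) == 1L) intensities <- rep(intensities, n)
  stopifnot(length(intensities) == n, length(t2) == n)
  if (any(!is.finite(shifts))) stop("shifts must be finite")
  if (any(intensities <= 0)) stop("all intensities must be > 0")
  if (any(t2 <= 0)) stop("all t2 must be > 0")
  structure(list(shifts = as.numeric(shifts), couplings = couplings,
                 intensities = as.numeric(intensities), t2 = as.numeric(t2)),
            class = "spin_system")
}

#' @export
print.spin_system <- function(x, ...) {
  n <- length(x$shifts)
  ncpl <- sum(abs(x$couplings[upper.tri(x$couplings)]) > 0)
  cat(sprintf("<spin_system> %d spin%s, %d coupling%s\n", n,
              if (n == 1L) "" else "s", ncpl, if (ncpl == 1L) "" else "s"))
  invisible(x)
}

n_spins <- function(system) length(system$shifts)

#' Random spin-system generator settings
#'
#' Ranges and rates used by [random_spin_system()]. These defaults define the
#' synthetic training and evaluation distribution: 1-12 spins, shifts uniform
#' over a window, a sparse random coupling topology (each pair coupled with
#' probability `p_couple`, |J| uniform in `j_range` with random sign), T2
#' log-uniform and intensities uniform.
#'
#' @param n_spins_range Integer range (min, max) for the number of spins.
#' @param shift_range Chemical-shift window (ppm), `c(min, max)`.
#' @param p_couple Probability that any given spin pair is coupled.
#' @param j_range Range of |J| in Hz for coupled pairs.
#' @param t2_range Range of T2 (s); sampled log-uniformly.
#' @param intensity_range Range of per-spin relative intensities.
#' @return A list of class `spin_gen_config`.
#' @export
spin_gen_config <- function(n_spins_range = c(1L, 12L),
                            shift_range = c(1.3, 4.7),
                            p_couple = 0.3,
                            j_range = c(1, 18),
                            t2_range = c(0.1, 2.0),
                            intensity_range = c(0.5, 1.5)) {
  chk <- function(r, nm) {
    if (length(r) != 2L || !all(is.finite(r)) || r[1] > r[2])
      stop("invalid range for ", nm)
  }
  chk(n_spins_range, "n_spins_range"); chk(shift_range, "shift_range")
  chk(j_range, "j_range"); chk(t2_range, "t2_range")
  chk(intensity_range, "intensity_range")
  if (n_spins_range[1] < 1L) stop("n_spins_range must start at 1 or more")
  if (p_couple < 0 || p_couple > 1) stop("p_couple must be in [0, 1]")
  if (any(t2_range <= 0)) stop("t2_range must be positive")
  structure(list(n_spins_range = as.integer(n_spins_range),
                 shift_range = shift_range, p_couple = p_couple,
                 j_range = j_range, t2_range = t2_range,
                 intensity_range = intensity_range),
            class = "spin_gen_config")
}

#' Draw a random spin system
#'
#' Samples a spin system from the synthetic distribution described by
#' [spin_gen_config()]. Fully determined by `rng_seed`.
#'
#' @param rng_seed Integer seed.
#' @param config A [spin_gen_config()].
#' @return A [spin_system()].
#' @examples
#' sys <- random_spin_system(1)
#' @export
random_spin_system <- function(rng_seed, config = spin_gen_config()) {
  if (!inherits(config, "spin_gen_config")) stop("config must be a spin_gen_config")
  with_seed(rng_seed, {
    n <- sample(config$n_spins_range[1]:config$n_spins_range[2], 1L)
    shifts <- stats::runif(n, config$shift_range[1], config$shift_range[2])
    J <- matrix(0, n, n)
    if (n > 1L) {
      for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
        if (stats::runif(1) < config$p_couple) {
          jij <- stats::runif(1, config$j_range[1], config$j_range[2]) *
            sample(c(-1, 1), 1L)
          J[i, j] <- J[j, i] <- jij
        }
      }
    }
    t2 <- exp(stats::runif(n, log(config$t2_range[1]), log(config$t2_range[2])))
    intens <- stats::runif(n, config$intensity_range[1], config$intensity_range[2])
    spin_system(shifts, J, intens, t2)
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
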