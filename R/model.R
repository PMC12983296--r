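#' Decoupler model configuration
#'
#' Architecture hyper-parameters of the decoupling network: the five real echo
#' spectra enter as channels; a stack of gated, dilated 1D convolutions with
#' residual and skip connections builds a receptive field wide enough to span
#' a full multiplet; a 1x1 head (plus a learned per-delay linear bypass of the
#' input spectra) emits the predicted pure-shift intensity, and a small probe
#' on detached trunk features emits the per-point log-variance. Defaults are
#' sized to train on a single CPU core at 1024-2048 points.
#'
#' @param n_input_channels Number of input spectra; must equal the echo
#'   schedule length (default 5).
#' @param n_points Grid length the model operates on (power of two).
#' @param dilation_schedule Dilation of each block; receptive-field half-width
#'   is `sum(dilations) * (kernel_width - 1) / 2` points.
#' @param kernel_width Odd convolution kernel width.
#' @param n_filters Channels carried through the trunk.
#' @return An object of class `model_config`.
#' @export
model_config <- function(n_input_channels = 5L, n_points = 1024L,
                         dilation_schedule = c(1L, 2L, 4L, 8L, 16L, 32L),
                         kernel_width = 3L, n_filters = 48L) {
  n_input_channels <- as.integer(n_input_channels)
  n_points <- as.integer(n_points)
  dilation_schedule <- as.integer(dilation_schedule)
  kernel_width <- as.integer(kernel_width)
  n_filters <- as.integer(n_filters)
  if (n_input_channels < 1L) stop("n_input_channels must be >= 1")
  if (length(dilation_schedule) == 0L || any(dilation_schedule < 1L))
    stop("dilation_schedule must be nonempty with all entries >= 1")
  if (kernel_width < 1L || kernel_width %% 2L == 0L)
    stop("kernel_width must be odd")
  if (n_points < 64L || bitwAnd(n_points, n_points - 1L) != 0L)
    stop("n_points must be a power of two >= 64")
  structure(list(n_input_channels = n_input_channels, n_points = n_points,
                 n_blocks = length(dilation_schedule),
                 kernel_width = kernel_width,
                 dilation_schedule = dilation_schedule,
                 n_filters = n_filters),
            class = "model_config")
}

#' Build an untrained decoupler
#'
#' Initializes network weights (Glorot-uniform) deterministically from `seed`.
#' The model predicts, per grid point, an intensity `mu` and a log-variance;
#' at inference the reported uncertainty is `sigma = sqrt(variance)` with a
#' floor of 1e-6 on the (normalized) variance.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `decoupler_model`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  params <- with_seed(seed, net_init_params(config))
  structure(list(config = config, params = params,
                 normalization = "max-abs of T=0 spectrum scaled to 1; outputs rescaled back",
                 version = "pureshiftnn-0.1.0", trained = FALSE),
            class = "decoupler_model")
}

#' @export
print.decoupler_model <- function(x, ...) {
  cat(sprintf("<decoupler_model> %d params, %d blocks x %d filters, %d-point axis, %s\n",
              net_n_params(x$params), x$config$n_blocks, x$config$n_filters,
              x$config$n_points, if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

# input normalization contract: scale by max |T=0| so the trained network
# always sees inputs of unit scale; outputs (mu, sigma) rescale linearly.
series_input_matrix <- function(series, config) {
  m <- series_matrix(series)          # n_points x n_delays
  if (ncol(m) != config$n_input_channels)
    stop("echo schedule length (", ncol(m),
         ") does not match model n_input_channels (", config$n_input_channels, ")")
  if (nrow(m) != config$n_points)
    stop("series axis length (", nrow(m),
         ") does not match model n_points (", config$n_points, ")")
  if (any(!is.finite(m))) stop("NaN or non-finite values in input series")
  t(m)                                # channels x points
}

#' Virtually decouple an echo series
#'
#' Applies the trained network to a five-spectrum echo series and returns the
#' pure-shift trace with per-point predicted uncertainties. Inputs are scaled
#' so the tallest absolute T = 0 intensity is 1 and outputs are rescaled back,
#' so the transform is exactly scale-equivariant: scaling the input by c > 0
#' scales both intensity and sigma by c.
#'
#' @param model A [build_model()] (normally trained via [train()]).
#' @param series An `echo_series` on the model's grid.
#' @return An object of class `pure_shift_result` with fields `axis`,
#'   `intensity`, `sigma` (strictly positive), `calibrated` (FALSE until
#'   [apply_calibration()]).
#' @export
decouple <- function(model, series) {
  stopifnot(inherits(model, "decoupler_model"), inherits(series, "echo_series"))
  X <- series_input_matrix(series, model$config)
  scale <- max(abs(X[1L, ]))
  if (scale == 0) {
    # degenerate all-zero input: zero trace with floor uncertainty
    n <- model$config$n_points
    return(new_pure_shift_result(series$axis, numeric(n), rep(1e-3, n)))
  }
  out <- net_forward(model$params, model$config, X / scale)
  sigma <- sqrt(pmax(exp(out$lv), 1e-6))
  new_pure_shift_result(series$axis, out$mu * scale, sigma * scale)
}

new_pure_shift_result <- function(axis, intensity, sigma, calibrated = FALSE) {
  stopifnot(length(intensity) == axis$n_points, length(sigma) == axis$n_points,
            all(sigma > 0))
  structure(list(axis = axis, intensity = as.numeric(intensity),
                 sigma = as.numeric(sigma), calibrated = calibrated),
            class = "pure_shift_result")
}

#' @export
print.pure_shift_result <- function(x, ...) {
  cat(sprintf("<pure_shift_result> %d points, max %.4g, median sigma %.3g, %s\n",
              x$axis$n_points, max(x$intensity), stats::median(x$sigma),
              if (isTRUE(x$calibrated)) "calibrated" else "uncalibrated"))
  invisible(x)
}

#' Slice-wise 2D decoupling
#'
#' Processes a stack of echo series (one per indirect-dimension slice of a 2D
#' experiment, already Fourier transformed along the indirect dimension)
#' independently: row k of the output is identical to
#' `decouple(model, plane[[k]])`.
#'
#' @param model A `decoupler_model`.
#' @param plane List of `echo_series`, all sharing one axis and schedule.
#' @return List of `pure_shift_result`, one per row.
#' @export
process_2d <- function(model, plane) {
  stopifnot(is.list(plane), length(plane) >= 1L)
  ax <- plane[[1L]]$axis
  sch <- plane[[1L]]$schedule$delays
  for (r in plane) {
    if (!inherits(r, "echo_series")) stop("plane must be a list of echo_series")
    if (!axes_equal(r$axis, ax) || !identical(r$schedule$delays, sch))
      stop("all rows of the plane must share one axis and echo schedule")
  }
  lapply(plane, function(row) decouple(model, row))
}

#' Save / load a decoupler model
#'
#' The archive stores the architecture config, the normalization descriptor,
#' a mandatory version string and the weights, so a model file is
#' self-describing.
#'
#' @param model A `decoupler_model`.
#' @param path File path.
#' @return `load_decoupler()` returns the model.
#' @export
save_decoupler <- function(model, path) {
  stopifnot(inherits(model, "decoupler_model"))
  obj <- list(format = "pureshiftnn-decoupler", version = model$version,
              config = unclass(model$config), normalization = model$normalization,
              trained = model$trained, params = model$params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_decoupler
#' @export
load_decoupler <- function(path) {
  if (!file.exists(path)) stop("no such model file: ", path)
  obj <- readRDS(path)
  if (!identical(obj$format, "pureshiftnn-decoupler") || is.null(obj$version))
    stop("not a decoupler model file: ", path)
  cfg <- do.call(model_config, obj$config[c("n_input_channels", "n_points",
                                            "dilation_schedule", "kernel_width",
                                            "n_filters")])
  structure(list(config = cfg, params = obj$params,
                 normalization = obj$normalization, version = obj$version,
                 trained = isTRUE(obj$trained)),
            class = "decoupler_model")
}
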