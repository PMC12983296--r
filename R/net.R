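# Native dilated-convolution network engine.
#
# The decoupler is a stack of gated, dilated 1D convolution blocks with
# residual and skip connections, followed by two 1x1 heads that emit the
# predicted pure-shift intensity (mu) and a per-point log-variance. All
# activations are channels x points matrices, so every convolution is one
# BLAS matmul against a tap-stacked ("im2col") view of its input; backprop is
# written out explicitly. This file is internal; the user-facing surface is
# in model.R / train.R.

# shift columns of x by s (positive: towards higher index), zero padding
shift_cols <- function(x, s) {
  n <- ncol(x)
  y <- matrix(0, nrow(x), n)
  if (s == 0L) return(x)
  if (abs(s) >= n) return(y)
  if (s > 0L) y[, (s + 1L):n] <- x[, 1L:(n - s)]
  else y[, 1L:(n + s)] <- x[, (1L - s):n]
  y
}

# stack kernel taps of x (C x N) for kernel width w and dilation d -> (w*C x N)
tap_stack <- function(x, w, d) {
  cc <- nrow(x); n <- ncol(x)
  half <- (w - 1L) %/% 2L
  out <- matrix(0, w * cc, n)
  for (k in 0:(w - 1L)) {
    s <- (k - half) * d
    rows <- (k * cc + 1L):((k + 1L) * cc)
    if (s == 0L) out[rows, ] <- x
    else if (s > 0L && s < n) out[rows, (s + 1L):n] <- x[, 1L:(n - s)]
    else if (s < 0L && -s < n) out[rows, 1L:(n + s)] <- x[, (1L - s):n]
  }
  out
}

# adjoint of tap_stack: fold (w*C x N) gradient back to (C x N)
tap_unstack <- function(g, w, d, cc) {
  n <- ncol(g)
  half <- (w - 1L) %/% 2L
  out <- matrix(0, cc, n)
  for (k in 0:(w - 1L)) {
    s <- (k - half) * d
    rows <- (k * cc + 1L):((k + 1L) * cc)
    if (s == 0L) out <- out + g[rows, ]
    else if (s > 0L && s < n) out[, 1L:(n - s)] <- out[, 1L:(n - s)] + g[rows, (s + 1L):n]
    else if (s < 0L && -s < n) out[, (1L - s):n] <- out[, (1L - s):n] + g[rows, 1L:(n + s)]
  }
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# initialize the flat parameter list for a model config (RNG must be seeded)
net_init_params <- function(cfg) {
  f <- cfg$n_filters; w <- cfg$kernel_width; cin <- cfg$n_input_channels
  p <- list()
  p$W_in <- glorot(f, w * cin, w * cin, f); p$b_in <- numeric(f)
  for (b in seq_along(cfg$dilation_schedule)) {
    p[[paste0("W_g", b)]] <- glorot(2L * f, w * f, w * f, 2L * f)
    p[[paste0("b_g", b)]] <- numeric(2L * f)
    p[[paste0("W_r", b)]] <- glorot(f, f, f, f)
    p[[paste0("b_r", b)]] <- numeric(f)
  }
  p$W_post <- glorot(f, f, f, f); p$b_post <- numeric(f)
  p$W_mu <- glorot(1L, f, f, 1L); p$b_mu <- 0
  # log-variance head: a small two-layer probe on *detached* trunk features
  # (no gradient flows from it into the trunk; see net_backward). Initialized
  # near a flat prior sigma of 1% of the normalized input scale with small
  # weights: the few peak points supply little gradient, so a large random
  # init there would leave sigma outliers that never train away.
  p[lv_param_names] <- probe_init_params(f)[lv_param_names]
  # learned per-delay linear combination of the input spectra feeding the
  # intensity head directly: a matched filter over the echo schedule (the
  # pure-shift trace is, to first order, a weighted projection of the five
  # J-modulated spectra); the conv stack then only learns the correction
  p$W_skip_in <- matrix(0, 1L, cin)
  p
}

net_n_params <- function(params) sum(vapply(params, length, integer(1)))

# forward pass; X is (n_input_channels x n_points). Returns list(mu, lv) and,
# if want_cache, the intermediates needed for the backward pass.
net_forward <- function(params, cfg, X, want_cache = FALSE) {
  w <- cfg$kernel_width; f <- cfg$n_filters
  nb <- length(cfg$dilation_schedule)
  P0 <- tap_stack(X, w, 1L)
  x <- params$W_in %*% P0 + params$b_in
  skip <- matrix(0, f, ncol(x))
  cache <- if (want_cache) list(P0 = P0, blocks = vector("list", nb))
  for (b in seq_len(nb)) {
    d <- cfg$dilation_schedule[b]
    P <- tap_stack(x, w, d)
    u <- params[[paste0("W_g", b)]] %*% P + params[[paste0("b_g", b)]]
    tg <- tanh(u[1:f, , drop = FALSE])
    sg <- sigmoid(u[(f + 1L):(2L * f), , drop = FALSE])
    z <- tg * sg
    skip <- skip + z
    x <- x + params[[paste0("W_r", b)]] %*% z + params[[paste0("b_r", b)]]
    if (want_cache) cache$blocks[[b]] <- list(P = P, tg = tg, sg = sg, z = z)
  }
  hpre <- params$W_post %*% skip + params$b_post
  hp <- pmax(hpre, 0)
  mu <- as.vector(params$W_mu %*% hp + params$b_mu + params$W_skip_in %*% X)
  # probe input: trunk features plus the explicit input noise floor — a good
  # denoising trunk learns noise-invariant features, so without this channel
  # the variance probe cannot see how noisy its input actually was
  hpl <- probe_features(hp, X)
  pf <- probe_forward(params, hpl)
  lv <- pf$lv
  if (want_cache) {
    cache$skip <- skip; cache$hp <- hp; cache$relu_mask <- hpre > 0
    cache$hpl <- hpl; cache$probe_fwd <- pf
    cache$X <- X
    list(mu = mu, lv = lv, cache = cache)
  } else list(mu = mu, lv = lv)
}

# robust noise floor of the (normalized) T = 0 input channel, appended to the
# trunk features as one constant row; log scale keeps the 20:1-1e5:1 span in
# a numerically friendly range for the probe
probe_features <- function(hp, X) {
  nz <- 1.4826 * stats::median(abs(diff(X[1L, ], differences = 2L))) / sqrt(6)
  rbind(hp, log(nz + 1e-9) - log(1e-9), deparse.level = 0)
}

# backward pass: gradients of a scalar loss with d loss / d mu = dmu,
# d loss / d lv = dlv (vectors). Returns flat gradient list matching params.
net_backward <- function(params, cfg, dmu, dlv, cache) {
  w <- cfg$kernel_width; f <- cfg$n_filters
  nb <- length(cfg$dilation_schedule)
  g <- list()
  dmu <- matrix(dmu, nrow = 1L); dlv <- matrix(dlv, nrow = 1L)
  hp <- cache$hp
  g$W_mu <- dmu %*% t(hp); g$b_mu <- sum(dmu)
  g$W_skip_in <- dmu %*% t(cache$X)
  # variance probe: trained on detached features — its gradient stops here
  g[lv_param_names] <- probe_backward(params, dlv, cache$hpl,
                                      cache$probe_fwd)[lv_param_names]
  dhp <- (t(params$W_mu) %*% dmu) * cache$relu_mask
  g$W_post <- dhp %*% t(cache$skip); g$b_post <- rowSums(dhp)
  dskip <- t(params$W_post) %*% dhp
  dx <- matrix(0, f, ncol(hp))
  for (b in rev(seq_len(nb))) {
    d <- cfg$dilation_schedule[b]
    cb <- cache$blocks[[b]]
    g[[paste0("W_r", b)]] <- dx %*% t(cb$z)
    g[[paste0("b_r", b)]] <- rowSums(dx)
    dz <- t(params[[paste0("W_r", b)]]) %*% dx + dskip
    dtg <- dz * cb$sg
    dsg <- dz * cb$tg
    du <- rbind(dtg * (1 - cb$tg^2), dsg * cb$sg * (1 - cb$sg))
    g[[paste0("W_g", b)]] <- du %*% t(cb$P)
    g[[paste0("b_g", b)]] <- rowSums(du)
    dx <- dx + tap_unstack(t(params[[paste0("W_g", b)]]) %*% du, w, d, f)
  }
  g$W_in <- dx %*% t(cache$P0); g$b_in <- rowSums(dx)
  g
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

# The variance probe trains at a higher rate than the trunk: its per-point
# NLL gradient is bounded (at most 1/2 per point) while the informative peak
# points are sparse, so at the trunk's learning rate it would still be
# settling when training ends.
lv_lr_multiplier <- 3

lv_param_names <- c("W_lv", "b_lv", "W_lv1", "b_lv1")

# fresh small-init probe parameters (RNG must be seeded by the caller); the
# +1 input column is the appended noise-floor feature (probe_features), which
# also bypasses the hidden layer straight into the output so the log-variance
# has a direct linear path in log-noise
probe_init_params <- function(f) {
  list(W_lv1 = matrix(stats::rnorm(f * (f + 1L), 0, 0.05), f, f + 1L),
       b_lv1 = numeric(f),
       W_lv = matrix(stats::rnorm(f + 1L, 0, 0.05), 1L, f + 1L),
       b_lv = log(1e-4))
}

# probe forward/backward on cached trunk features (trunk frozen); used by the
# probe-refinement phase after the mean head has converged
probe_forward <- function(q, hpl) {
  hl_pre <- q$W_lv1 %*% hpl + q$b_lv1
  hl <- pmax(hl_pre, 0)
  nzrow <- hpl[nrow(hpl), , drop = FALSE]
  hla <- rbind(hl, nzrow, deparse.level = 0)
  list(lv = as.vector(q$W_lv %*% hla + q$b_lv), hl = hl, hla = hla,
       mask = hl_pre > 0)
}

probe_backward <- function(q, dlv, hpl, fwd) {
  dlv <- matrix(dlv, nrow = 1L)
  f <- nrow(fwd$hl)
  g <- list()
  g$W_lv <- dlv %*% t(fwd$hla); g$b_lv <- sum(dlv)
  dhl <- (t(q$W_lv[, 1:f, drop = FALSE]) %*% dlv) * fwd$mask
  g$W_lv1 <- dhl %*% t(hpl); g$b_lv1 <- rowSums(dhl)
  g
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    lrn <- if (nm %in% c("W_lv", "b_lv", "W_lv1", "b_lv1"))
      lr * lv_lr_multiplier else lr
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lrn * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
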