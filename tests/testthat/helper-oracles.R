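# Independent oracles used across tests.

# Exact two-spin transition spectrum by diagonalizing the 4x4 Hamiltonian
# H = nu_a*Iz1 + nu_b*Iz2 + J*(I1 . I2) in Hz, intensities from |<f|Ix-|i>|^2
# between eigenstates differing by one unit of total Mz. Independent of the
# closed-form expressions used in the package.
two_spin_hamiltonian_spectrum <- function(nu_a, nu_b, j) {
  sx <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  sy <- matrix(c(0, 0.5i, -0.5i, 0), 2, 2)
  sz <- diag(c(0.5, -0.5))
  id <- diag(2)
  kp <- kronecker
  H <- nu_a * kp(sz, id) + nu_b * kp(id, sz) +
    j * (kp(sx, sx) + kp(sy, sy) + kp(sz, sz))
  eig <- eigen((H + Conj(t(H))) / 2)   # Hermitian
  E <- eig$values; V <- eig$vectors
  Mz <- kp(sz, id) + kp(id, sz)
  mz <- Re(diag(Conj(t(V)) %*% Mz %*% V))
  Ixt <- kp(sx, id) + kp(id, sx)
  lines <- list()
  for (a in 1:4) for (b in 1:4) {
    if (abs(mz[a] - mz[b] - 1) < 1e-8) {     # single-quantum transition
      amp <- abs(Conj(t(V[, b, drop = FALSE])) %*% Ixt %*% V[, a, drop = FALSE])^2
      if (amp > 1e-12)
        lines[[length(lines) + 1L]] <- c(freq = E[a] - E[b], inten = Re(amp))
    }
  }
  m <- do.call(rbind, lines)
  m <- m[order(m[, 1]), , drop = FALSE]
  # merge degenerate transitions
  out <- NULL
  for (r in seq_len(nrow(m))) {
    if (!is.null(out) && abs(m[r, 1] - out[nrow(out), 1]) < 1e-8)
      out[nrow(out), 2] <- out[nrow(out), 2] + m[r, 2]
    else out <- rbind(out, m[r, , drop = FALSE])
  }
  data.frame(frequency = out[, 1], intensity = out[, 2] / sum(out[, 2]))
}

# tiny default grid used throughout the unit tests (fast)
test_axis <- function(n = 512L) spectral_axis(n, 3200, 800, 3)

# a simple isolated doublet system (J Hz, long T2 unless given)
doublet_system <- function(j = 10, t2 = 1e5, shifts = c(2.5, 4.0)) {
  spin_system(shifts, matrix(c(0, j, j, 0), 2, 2), t2 = t2)
}

# 1:2:1 triplet: spin 1 coupled equally to two mutually uncoupled partners
triplet_system <- function(j = 7, t2 = 1e5) {
  J <- matrix(0, 3, 3)
  J[1, 2] <- J[2, 1] <- j
  J[1, 3] <- J[3, 1] <- j
  spin_system(c(2.5, 4.0, 4.4), J, t2 = t2)
}
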