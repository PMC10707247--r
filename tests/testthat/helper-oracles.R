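# Independent oracles: closed-form single-oscillator response and a
# hand-written dense Gaussian elimination, both kept free of the package's
# solver path.

# Analytic harmonic velocity of one mass on one spring and one viscous damper
# driven by force F: v = i w F / (k - w^2 m + i w c).
sdof_velocity <- function(k, m, c, force, freq) {
  w <- 2 * pi * freq
  1i * w * force / (k - w^2 * m + 1i * w * c)
}

# Velocity-resonance frequency of the same oscillator: exactly sqrt(k/m)/2pi
# for viscous damping.
sdof_resonance_hz <- function(k, m) sqrt(k / m) / (2 * pi)

# Brute-force complex Gaussian elimination with partial pivoting.
dense_gauss_solve <- function(A, b) {
  n <- nrow(A)
  A <- cbind(A, b)
  for (col in seq_len(n - 1L)) {
    piv <- which.max(Mod(A[col:n, col])) + col - 1L
    if (Mod(A[piv, col]) == 0) stop("singular matrix in oracle")
    if (piv != col) A[c(col, piv), ] <- A[c(piv, col), ]
    for (row in (col + 1L):n) {
      fac <- A[row, col] / A[col, col]
      A[row, ] <- A[row, ] - fac * A[col, ]
    }
  }
  x <- complex(n)
  for (row in n:1) {
    x[row] <- (A[row, n + 1L] - sum(A[row, seq_len(n)][-(1:row)] * x[-(1:row)])) / A[row, row]
  }
  x
}

# Maxwell storage/loss moduli summed arm by arm, written independently of the
# package implementation (no vapply over a shared kernel).
maxwell_oracle <- function(e_inf, e, tau, freq) {
  w <- 2 * pi * freq
  storage <- e_inf
  loss <- 0
  for (i in seq_along(e)) {
    x <- (w * tau[i])^2
    storage <- storage + e[i] * x / (1 + x)
    loss <- loss + e[i] * (w * tau[i]) / (1 + x)
  }
  complex(real = storage, imaginary = loss)
}
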