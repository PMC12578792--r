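# Periodised orthogonal Daubechies-2 (4-tap) wavelet transform, operating
# column-wise on a matrix of series. Written in-package because the analysis
# chain needs only this one transform (HOMER-style motion correction zeroes
# outlying detail coefficients and reconstructs).

db2_filters <- function() {
  h <- c(0.482962913144690, 0.836516303737469,
         0.224143868042013, -0.129409522550921)
  g <- c(h[4], -h[3], h[2], -h[1])  # quadrature mirror
  list(h = h, g = g)
}

# One analysis step: X is m x p with m even; returns approximation and
# detail matrices of size (m/2) x p (periodic boundary handling).
dwt_step <- function(X) {
  f <- db2_filters()
  m <- nrow(X)
  m2 <- m %/% 2
  A <- matrix(0, m2, ncol(X)); D <- A
  base <- 2 * (seq_len(m2) - 1)
  for (j in 1:4) {
    pos <- (base + (j - 1)) %% m + 1
    A <- A + f$h[j] * X[pos, , drop = FALSE]
    D <- D + f$g[j] * X[pos, , drop = FALSE]
  }
  list(A = A, D = D)
}

# Transpose (synthesis) step: exact inverse of dwt_step for orthonormal
# filters.
idwt_step <- function(A, D) {
  f <- db2_filters()
  m2 <- nrow(A)
  m <- 2 * m2
  Y <- matrix(0, m, ncol(A))
  base <- 2 * (seq_len(m2) - 1)
  for (j in 1:4) {
    pos <- (base + (j - 1)) %% m + 1
    Y[pos, ] <- Y[pos, ] + f$h[j] * A + f$g[j] * D
  }
  Y
}

dwt_forward <- function(X, levels) {
  details <- vector("list", levels)
  cur <- X
  for (l in seq_len(levels)) {
    s <- dwt_step(cur)
    details[[l]] <- s$D
    cur <- s$A
  }
  list(approx = cur, details = details)
}

dwt_inverse <- function(dec) {
  cur <- dec$approx
  for (l in rev(seq_along(dec$details))) {
    cur <- idwt_step(cur, dec$details[[l]])
  }
  cur
}

# Zero detail coefficients lying outside [q1 - k*IQR, q3 + k*IQR] of their
# level's per-series coefficient distribution, then reconstruct. Series are
# reflection-padded to a multiple of 2^levels and trimmed afterwards.
dwt_iqr_denoise <- function(X, iqr_mult, levels) {
  n0 <- nrow(X)
  block <- 2^levels
  if (n0 < 4 * block) {
    warning("series shorter than wavelet filter support; returned unchanged")
    return(X)
  }
  n <- ceiling(n0 / block) * block
  if (n > n0) {
    pad <- X[seq(n0, by = -1, length.out = n - n0), , drop = FALSE]
    X <- rbind(X, pad)
  }
  dec <- dwt_forward(X, levels)
  for (l in seq_len(levels)) {
    D <- dec$details[[l]]
    for (p in seq_len(ncol(D))) {
      q <- stats::quantile(D[, p], c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      out <- D[, p] < q[1] - iqr_mult * iqr | D[, p] > q[2] + iqr_mult * iqr
      D[out, p] <- 0
    }
    dec$details[[l]] <- D
  }
  dwt_inverse(dec)[seq_len(n0), , drop = FALSE]
}
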