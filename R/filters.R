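# Column-wise IIR filtering. Reproduces signal::filter / signal::filtfilt
# exactly (zero initial conditions, zero-padding by 2*max(length(a),
# length(b)) before the backward pass) but runs on whole matrices so a
# recording's channel x wavelength series are filtered in one call.

iir_mat <- function(b, a, X) {
  nb <- length(b)
  Xp <- rbind(matrix(0, nb - 1, ncol(X)), X)
  Y <- stats::filter(Xp, b, method = "convolution", sides = 1)
  Y <- Y[nb:nrow(Xp), , drop = FALSE]
  if (length(a) > 1) Y <- stats::filter(Y, -a[-1], method = "recursive")
  matrix(as.numeric(Y), nrow(X), ncol(X))
}

filtfilt_mat <- function(b, a, X) {
  npad <- 2 * max(length(a), length(b))
  Y <- iir_mat(b, a, rbind(X, matrix(0, npad, ncol(X))))
  Y <- iir_mat(b, a, Y[nrow(Y):1, , drop = FALSE])
  Y[nrow(Y):1, , drop = FALSE][seq_len(nrow(X)), , drop = FALSE]
}

# zero-phase 3rd-order Butterworth band-pass as two cascaded sections,
# columns = series
bandpass_mat <- function(X, fs, low_hz, high_hz) {
  hp <- signal::butter(3, low_hz / (fs / 2), type = "high")
  lp <- signal::butter(3, high_hz / (fs / 2), type = "low")
  filtfilt_mat(lp$b, lp$a, filtfilt_mat(hp$b, hp$a, X))
}
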