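#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities, the standard adult-form HRF, with a
#' configurable time-to-peak. Used by the synthetic forward model; infant
#' timing is approximated by keeping the canonical shape and exposing the
#' peak delay as a parameter.
#'
#' @param t Time grid in seconds (non-negative values contribute).
#' @param peak_delay_s Time-to-peak of the positive lobe in seconds.
#' @param undershoot_delay_s Time-to-peak of the undershoot lobe.
#' @param undershoot_ratio Amplitude of the undershoot relative to the peak.
#' @return Numeric vector of the same length as `t`, with maximum 1.
#' @examples
#' h <- hrf_double_gamma(seq(0, 30, by = 0.2))
#' seq(0, 30, by = 0.2)[which.max(h)]  # ~5.5 s
#' @export
hrf_double_gamma <- function(t, peak_delay_s = 5.5, undershoot_delay_s = 15,
                             undershoot_ratio = 1 / 6) {
  assert_that(peak_delay_s > 0 && undershoot_delay_s > peak_delay_s,
              "undershoot delay must exceed peak delay")
  # gamma density with unit rate peaks at shape - 1, so shape = delay + 1
  a1 <- peak_delay_s + 1
  a2 <- undershoot_delay_s + 1
  h <- ifelse(t >= 0,
              stats::dgamma(t, shape = a1, rate = 1) -
                undershoot_ratio * stats::dgamma(t, shape = a2, rate = 1),
              0)
  h / max(h)
}

# HRF kernel sampled at fs, normalised so that convolution with a reference
# 10-s boxcar peaks at exactly 1 (block-design amplitude convention).
hrf_kernel <- function(fs, peak_delay_s = 5.5, undershoot_delay_s = 15,
                       undershoot_ratio = 1 / 6, support_s = 32) {
  tt <- seq(0, support_s, by = 1 / fs)
  h <- hrf_double_gamma(tt, peak_delay_s, undershoot_delay_s, undershoot_ratio)
  box <- rep(1, round(10 * fs))
  ref <- stats::convolve(c(box, numeric(length(h))), rev(h), type = "open") / fs
  h / max(ref)
}
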