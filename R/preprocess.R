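#' Preprocessing parameters
#'
#' Parameters of the HOMER-style preprocessing chain: channel pruning on raw
#' intensity amplitude, wavelet and spline motion correction on optical
#' density, zero-phase band-pass, and modified Beer-Lambert inversion.
#'
#' @param intensity_bounds Channels whose mean raw intensity (either
#'   wavelength) falls outside these device-unit bounds are pruned.
#' @param sd_range_mm Source-detector distance range (mm) a channel must lie
#'   in to be kept.
#' @param wavelet_iqr IQR multiplier of the wavelet outlier rule.
#' @param wavelet_levels Decomposition depth of the db2 transform.
#' @param spline_p Smoothing parameter of the spline correction (csaps
#'   convention; mapped to `smooth.spline` via `lambda = (1-p)/p`).
#' @param bandpass_hz High-pass and low-pass corner frequencies (Hz).
#' @param dpf Differential pathlength factor per wavelength.
#' @param min_data_s A recording shorter than this (seconds) is rejected.
#' @param max_bad_channel_frac A recording with a larger pruned-channel
#'   fraction is rejected.
#' @param motion_window_s,motion_k Moving-SD motion detector: window length
#'   (s) and threshold multiplier over the median moving SD.
#' @param do_wavelet,do_spline,do_bandpass Stage switches.
#' @export
preproc_params <- function(intensity_bounds = c(2, 10),
                           sd_range_mm = c(0, 45),
                           wavelet_iqr = 0.8,
                           wavelet_levels = 4,
                           spline_p = 0.99,
                           bandpass_hz = c(0.01, 1.0),
                           dpf = c(5.1, 5.1),
                           min_data_s = 300,
                           max_bad_channel_frac = 0.5,
                           motion_window_s = 1,
                           motion_k = 5,
                           do_wavelet = TRUE,
                           do_spline = TRUE,
                           do_bandpass = TRUE) {
  assert_that(intensity_bounds[1] < intensity_bounds[2],
              "intensity_bounds must be increasing")
  assert_that(bandpass_hz[1] > 0 && bandpass_hz[1] < bandpass_hz[2],
              "band-pass corners must satisfy 0 < low < high")
  assert_that(spline_p > 0 && spline_p < 1, "spline_p must lie in (0, 1)")
  assert_that(wavelet_iqr >= 0, "wavelet_iqr must be >= 0")
  structure(as.list(environment()), class = "preproc_params")
}

#' Prune channels on raw intensity and distance; reject unusable recordings
#'
#' A channel is flagged bad when its temporal-mean raw intensity at either
#' wavelength lies outside `intensity_bounds`, or its source-detector
#' distance lies outside `sd_range_mm`. The whole recording is rejected
#' (classed error `natfnirs_recording_rejected`, distinct from per-channel
#' pruning) when it is shorter than `min_data_s` or when more than
#' `max_bad_channel_frac` of channels are bad.
#'
#' @param rec A `nat_recording`.
#' @param params A [preproc_params()].
#' @return The recording with an updated `channel_ok` mask.
#' @export
prune_channels <- function(rec, params = preproc_params()) {
  stopifnot(inherits(rec, "nat_recording"))
  n_ch <- dim(rec$intensity)[1]
  dur_s <- dim(rec$intensity)[3] / rec$sample_rate_hz
  if (dur_s < params$min_data_s) {
    stopf("recording %s rejected: %.0f s of data < minimum %g s",
          rec$participant_id, dur_s, params$min_data_s,
          class = "natfnirs_recording_rejected")
  }
  mean_i <- apply(rec$intensity, c(1, 2), mean)
  in_bounds <- mean_i >= params$intensity_bounds[1] &
    mean_i <= params$intensity_bounds[2]
  ok <- rec$channel_ok & in_bounds[, 1] & in_bounds[, 2] &
    rec$distance_mm >= params$sd_range_mm[1] &
    rec$distance_mm <= params$sd_range_mm[2]
  if (mean(!ok) > params$max_bad_channel_frac) {
    stopf("recording %s rejected: %d/%d channels pruned (> %.0f%%)",
          rec$participant_id, sum(!ok), n_ch,
          100 * params$max_bad_channel_frac,
          class = "natfnirs_recording_rejected")
  }
  rec$channel_ok <- ok
  rec
}

#' Convert raw intensity to optical density
#'
#' OD(t) = -log10(I(t) / mean(I)) per channel and wavelength, referencing
#' each series to its own temporal mean.
#'
#' @param rec A `nat_recording` (positive intensities on usable channels).
#' @return An object of class `nat_od` carrying the channel x wavelength x
#'   time OD array plus channel metadata.
#' @export
intensity_to_od <- function(rec) {
  stopifnot(inherits(rec, "nat_recording"))
  ok <- rec$channel_ok
  if (any(rec$intensity[ok, , , drop = FALSE] <= 0))
    stopf("non-positive intensity sample on a usable channel")
  od <- rec$intensity
  for (w in seq_len(dim(od)[2])) {
    m <- apply(od[, w, , drop = FALSE], 1, mean)
    od[, w, ] <- -log10(od[, w, ] / m)
  }
  od[!ok, , ] <- NA_real_
  structure(list(
    participant_id = rec$participant_id,
    od = od,
    wavelengths_nm = rec$wavelengths_nm,
    sample_rate_hz = rec$sample_rate_hz,
    distance_mm = rec$distance_mm,
    dpf = rec$dpf,
    channel_ok = ok,
    time_s = rec$time_s
  ), class = "nat_od")
}

#' Wavelet motion correction
#'
#' db2 discrete wavelet decomposition per channel/wavelength series; detail
#' coefficients lying more than `iqr_mult` interquartile ranges outside the
#' coefficient distribution's quartiles are zeroed before reconstruction.
#'
#' @param od A `nat_od`.
#' @param iqr_mult IQR multiplier (0.8 in the target protocol).
#' @param levels Decomposition depth.
#' @return The corrected `nat_od`.
#' @export
wavelet_correct <- function(od, iqr_mult = 0.8, levels = 4) {
  stopifnot(inherits(od, "nat_od"))
  ok <- which(od$channel_ok)
  if (!length(ok)) return(od)
  n_t <- dim(od$od)[3]
  for (w in seq_len(dim(od$od)[2])) {
    X <- t(od$od[ok, w, , drop = TRUE])
    if (length(ok) == 1) X <- matrix(od$od[ok, w, ], ncol = 1)
    od$od[ok, w, ] <- t(dwt_iqr_denoise(X, iqr_mult, levels))
  }
  od
}

#' Detect motion segments with a moving-SD rule
#'
#' Flags samples where the moving standard deviation (window
#' `window_s`) of either wavelength exceeds `k` times its median, then
#' dilates each flagged segment by one window so corrections cover the full
#' excursion.
#'
#' @param od A `nat_od`.
#' @param window_s Moving window length in seconds.
#' @param k Threshold multiplier over the median moving SD.
#' @return Logical channel x time matrix of motion samples.
#' @export
detect_motion <- function(od, window_s = 1, k = 5) {
  stopifnot(inherits(od, "nat_od"))
  fs <- od$sample_rate_hz
  w <- max(3L, round(window_s * fs))
  n_ch <- dim(od$od)[1]; n_t <- dim(od$od)[3]
  mask <- matrix(FALSE, n_ch, n_t)
  kern <- rep(1 / w, w)
  ok <- which(od$channel_ok)
  if (!length(ok)) return(mask)
  flag_ok <- matrix(FALSE, length(ok), n_t)
  for (wl in seq_len(dim(od$od)[2])) {
    X <- t(od$od[ok, wl, , drop = TRUE])
    if (length(ok) == 1) X <- matrix(od$od[ok, wl, ], ncol = 1)
    mu <- stats::filter(X, kern, sides = 2)
    mu2 <- stats::filter(X^2, kern, sides = 2)
    s <- sqrt(pmax(matrix(as.numeric(mu2 - mu^2), n_t, length(ok)), 0))
    med <- apply(s, 2, stats::median, na.rm = TRUE)
    hit <- !is.na(s) & sweep(s, 2, k * pmax(med, .Machine$double.eps), ">")
    flag_ok <- flag_ok | t(hit)
  }
  for (i in seq_along(ok)) {
    if (!any(flag_ok[i, ])) next
    # dilate by one window on each side
    idx <- which(flag_ok[i, ])
    flag <- flag_ok[i, ]
    lo <- pmax(idx - w, 1L); hi <- pmin(idx + w, n_t)
    for (j in seq_along(idx)) flag[lo[j]:hi[j]] <- TRUE
    mask[ok[i], ] <- flag
  }
  mask
}

#' Spline motion correction within detected segments
#'
#' Within each masked segment a smoothing spline (csaps-style parameter `p`,
#' mapped to `smooth.spline`'s `lambda = (1 - p)/p`) is fitted and
#' subtracted; the segment is re-anchored to continue from the preceding
#' sample, and all subsequent samples are level-shifted so the series stays
#' continuous (this removes persistent baseline shifts). Samples outside
#' masked segments are untouched except for that level re-anchoring.
#'
#' @param od A `nat_od`.
#' @param p Smoothing parameter in (0, 1).
#' @param mask Logical channel x time matrix from [detect_motion()]; if
#'   `NULL` it is computed with defaults. An empty mask yields the identity.
#' @param min_seg Segments shorter than this many samples are replaced by
#'   their anchor level rather than spline-fitted.
#' @return The corrected `nat_od`.
#' @export
spline_correct <- function(od, p = 0.99, mask = NULL, min_seg = 8L) {
  stopifnot(inherits(od, "nat_od"))
  if (is.null(mask)) mask <- detect_motion(od)
  if (!any(mask)) return(od)
  lambda <- (1 - p) / p
  n_t <- dim(od$od)[3]
  for (ch in which(od$channel_ok)) {
    if (!any(mask[ch, ])) next
    runs <- rle(mask[ch, ])
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    for (wl in seq_len(dim(od$od)[2])) {
      y <- od$od[ch, wl, ]
      for (r in which(runs$values)) {
        i1 <- starts[r]; i2 <- ends[r]; L <- i2 - i1 + 1L
        seg <- y[i1:i2]
        f <- if (L >= min_seg) {
          fit <- try(stats::smooth.spline(seq_len(L), seg, lambda = lambda),
                     silent = TRUE)
          if (inherits(fit, "try-error")) seg
          else stats::predict(fit, seq_len(L))$y
        } else seg
        left <- if (i1 > 1) y[i1 - 1] else f[1]
        y[i1:i2] <- (seg - f) + left
        if (i2 < n_t) y[(i2 + 1):n_t] <- y[(i2 + 1):n_t] + (left - f[L])
      }
      od$od[ch, wl, ] <- y
    }
  }
  od
}

#' Zero-phase band-pass filter
#'
#' Separate 3rd-order Butterworth high-pass and low-pass sections, each
#' applied forward and backward (zero-phase, numerically identical to
#' `signal::filtfilt`) so epoch timing is not phase-shifted. Removes DC by
#' construction.
#'
#' @param od A `nat_od`.
#' @param low_hz,high_hz Pass-band corners in Hz (defaults 0.01 and 1).
#' @return The filtered `nat_od`.
#' @export
bandpass <- function(od, low_hz = 0.01, high_hz = 1.0) {
  stopifnot(inherits(od, "nat_od"))
  fs <- od$sample_rate_hz
  assert_that(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2,
              "band [%g, %g] Hz infeasible at fs = %g Hz", low_hz, high_hz, fs)
  ok <- which(od$channel_ok)
  if (!length(ok)) return(od)
  n_wl <- dim(od$od)[2]
  for (wl in seq_len(n_wl)) {
    X <- t(od$od[ok, wl, , drop = TRUE])
    if (length(ok) == 1) X <- matrix(od$od[ok, wl, ], ncol = 1)
    od$od[ok, wl, ] <- t(bandpass_mat(X, fs, low_hz, high_hz))
  }
  od
}

#' Modified Beer-Lambert inversion to chromophore concentrations
#'
#' Solves, per channel and sample, the 2x2 linear system
#' `dOD(lambda) = (eps_HbO(lambda) dHbO + eps_HbR(lambda) dHbR) * d * DPF(lambda)`
#' for the HbO/HbR concentration changes.
#'
#' @param od A `nat_od`.
#' @param dpf Differential pathlength factors (defaults from the recording).
#' @param distance_mm Source-detector distance (default from the recording).
#' @param extinction 2x2 extinction matrix (rows wavelengths, columns
#'   HbO/HbR); defaults to the packaged table at the recording wavelengths.
#' @return An object of class `hb_series` with `hbo`/`hbr` channel x time
#'   matrices in micromolar.
#' @export
mbll <- function(od, dpf = NULL, distance_mm = NULL, extinction = NULL) {
  stopifnot(inherits(od, "nat_od"))
  if (is.null(dpf)) dpf <- od$dpf
  if (is.null(distance_mm)) distance_mm <- od$distance_mm
  if (is.null(extinction)) extinction <- extinction_coefficients(od$wavelengths_nm)
  E <- rbind(extinction[1, c("eps_hbo", "eps_hbr")],
             extinction[2, c("eps_hbo", "eps_hbr")])
  if (rcond(E) < 1e-10) stopf("extinction matrix is singular at these wavelengths")
  Einv <- solve(E)
  d_cm <- distance_mm / 10
  S1 <- od$od[, 1, , drop = TRUE] / (d_cm * dpf[1])
  S2 <- od$od[, 2, , drop = TRUE] / (d_cm * dpf[2])
  if (is.null(dim(S1))) { S1 <- matrix(S1, nrow = 1); S2 <- matrix(S2, nrow = 1) }
  hbo <- (Einv[1, 1] * S1 + Einv[1, 2] * S2) * 1e6
  hbr <- (Einv[2, 1] * S1 + Einv[2, 2] * S2) * 1e6
  hbo[!od$channel_ok, ] <- NA_real_
  hbr[!od$channel_ok, ] <- NA_real_
  structure(list(
    participant_id = od$participant_id,
    hbo = hbo, hbr = hbr,
    sample_rate_hz = od$sample_rate_hz,
    channel_ok = od$channel_ok,
    time_s = od$time_s
  ), class = "hb_series")
}

#' Run the full preprocessing chain
#'
#' Pruning, optical density, optional wavelet and spline motion correction,
#' optional zero-phase band-pass, and Beer-Lambert inversion, in the
#' protocol's order. Deterministic.
#'
#' @param rec A `nat_recording`.
#' @param params A [preproc_params()].
#' @return An `hb_series` with a `preproc` attribute recording stage
#'   bookkeeping (pruned channel count, motion samples flagged).
#' @export
preprocess <- function(rec, params = preproc_params()) {
  rec <- prune_channels(rec, params)
  od <- intensity_to_od(rec)
  if (params$do_wavelet)
    od <- wavelet_correct(od, params$wavelet_iqr, params$wavelet_levels)
  n_motion <- 0L
  if (params$do_spline) {
    mask <- detect_motion(od, params$motion_window_s, params$motion_k)
    n_motion <- sum(mask)
    od <- spline_correct(od, params$spline_p, mask)
  }
  if (params$do_bandpass)
    od <- bandpass(od, params$bandpass_hz[1], params$bandpass_hz[2])
  hb <- mbll(od, params$dpf)
  attr(hb, "preproc") <- list(n_pruned = sum(!rec$channel_ok),
                              n_motion_samples = n_motion)
  hb
}

#' @export
print.hb_series <- function(x, ...) {
  cat(sprintf("<hb_series> %s: %d channels x %d samples @ %g Hz (uM); %d channels ok\n",
              x$participant_id, nrow(x$hbo), ncol(x$hbo), x$sample_rate_hz,
              sum(x$channel_ok)))
  invisible(x)
}
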