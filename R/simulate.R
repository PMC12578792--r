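#' Simulation configuration for synthetic naturalistic fNIRS sessions
#'
#' Bundles every knob of the synthetic-data generator: the behavioral
#' look-bout process, the hemodynamic forward model, physiological noise and
#' motion artifacts, and the optical geometry. Defaults emulate the study
#' design the package targets: 12 infants, one 20-minute free-play session
#' each, a 44-channel two-wavelength array (763/841 nm) sampled at 5 Hz with
#' ~20 mm source-detector separation, and sustained-attention hemodynamic
#' responses time-locked 5 s into looks at three adjacent left
#' temporo-parietal channels.
#'
#' @param n_participants Number of simulated infants.
#' @param n_channels Number of measurement channels.
#' @param sample_rate_hz Sampling rate in Hz.
#' @param session_length_s Session duration in seconds.
#' @param active_channels Channel indices carrying the attention-locked
#'   response (default 9:11, the left-TPJ channels of the packaged ROI map).
#' @param effect_amplitude_uM Peak concentration change of HbO in micromolar
#'   for a reference 10-s sustained-attention episode.
#' @param hrf_peak_delay_s,hrf_undershoot_delay_s,hrf_undershoot_ratio
#'   Double-gamma HRF shape parameters (seconds, seconds, ratio).
#' @param hrf_onset_lag_s Latency of sustained attention into a look: the
#'   neural boxcar starts this many seconds after look onset.
#' @param hbr_ratio HbR is modeled as `-hbr_ratio` times HbO.
#' @param sustained_threshold_s Minimum look duration that evokes a response.
#' @param noise A [noise_spec()].
#' @param artifact An [artifact_spec()].
#' @param bout_duration_lognorm,gap_duration_lognorm Named `c(meanlog, sdlog)`
#'   of the lognormal look-bout and inter-look gap durations (seconds).
#' @param target_weights Named sampling weights of look targets (toy-dominant).
#' @param baseline_intensity Raw detector intensity at rest, device units.
#' @param distance_mm Source-detector separation in millimetres.
#' @param wavelengths_nm The two measurement wavelengths.
#' @param dpf Differential pathlength factor per wavelength.
#' @param seed Integer seed; every generator output is deterministic given
#'   the config (participant streams are derived from it).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_participants = 12,
                       n_channels = 44,
                       sample_rate_hz = 5,
                       session_length_s = 1200,
                       active_channels = 9:11,
                       effect_amplitude_uM = 0.75,
                       hrf_peak_delay_s = 5.5,
                       hrf_undershoot_delay_s = 15,
                       hrf_undershoot_ratio = 1 / 6,
                       hrf_onset_lag_s = 5,
                       hbr_ratio = 1 / 3,
                       sustained_threshold_s = 8,
                       noise = noise_spec(),
                       artifact = artifact_spec(),
                       bout_duration_lognorm = c(meanlog = 1.0, sdlog = 0.9),
                       gap_duration_lognorm = c(meanlog = 1.3, sdlog = 0.7),
                       target_weights = c(toy = 0.60, mom = 0.10, mbody = 0.10,
                                          bbody = 0.08, cables = 0.05,
                                          curtain = 0.04, door = 0.03),
                       baseline_intensity = 5,
                       distance_mm = 20,
                       wavelengths_nm = c(763, 841),
                       dpf = c(5.1, 5.1),
                       seed = 1L) {
  assert_that(is_count(n_participants) && n_participants >= 1, "n_participants must be a positive count")
  assert_that(is_count(n_channels) && n_channels >= 1, "n_channels must be a positive count")
  assert_that(sample_rate_hz > 0, "sample_rate_hz must be positive")
  assert_that(session_length_s >= 0, "session_length_s must be non-negative")
  assert_that(length(active_channels) == 0 ||
                (all(active_channels >= 1) && all(active_channels <= n_channels)),
              "active_channels must lie in 1..n_channels")
  assert_that(effect_amplitude_uM >= 0, "effect_amplitude_uM must be >= 0")
  assert_that(hrf_onset_lag_s >= 0 && hrf_peak_delay_s > 0, "HRF timing must be positive")
  assert_that(all(c("meanlog", "sdlog") %in% names(bout_duration_lognorm)) &&
                all(c("meanlog", "sdlog") %in% names(gap_duration_lognorm)),
              "duration parameters must be named c(meanlog=, sdlog=)")
  assert_that(all(target_weights > 0) && !is.null(names(target_weights)),
              "target_weights must be a named positive vector")
  assert_that(length(wavelengths_nm) == 2 && length(dpf) == 2,
              "exactly two wavelengths / DPF values are supported")
  assert_that(baseline_intensity > 0 && distance_mm > 0, "geometry must be positive")
  stopifnot(inherits(noise, "noise_spec"), inherits(artifact, "artifact_spec"))
  structure(as.list(environment()), class = "sim_config")
}

#' Physiological noise specification
#'
#' Amplitudes are on the optical-density scale. The drift component is a
#' normalised random walk (1/f^2-type spectrum); Mayer-wave and respiratory
#' components are sinusoids with channel-random phase; `white_sd` is
#' per-sample measurement noise. `participant_scale_sdlog` introduces
#' between-infant heterogeneity: each participant's whole noise budget is
#' multiplied by one lognormal factor, mimicking the large SNR differences
#' typical of infant recordings.
#'
#' @param drift_sd,mayer_amp,resp_amp,white_sd Amplitudes (OD units).
#' @param mayer_freq_hz,resp_freq_hz Oscillation frequencies (Hz).
#' @param participant_scale_sdlog sdlog of the per-participant scale factor.
#' @export
noise_spec <- function(drift_sd = 0.010, mayer_amp = 0.002, mayer_freq_hz = 0.1,
                       resp_amp = 0.001, resp_freq_hz = 0.4, white_sd = 0.004,
                       participant_scale_sdlog = 0.3) {
  assert_that(all(c(drift_sd, mayer_amp, resp_amp, white_sd) >= 0),
              "noise amplitudes must be >= 0")
  assert_that(mayer_freq_hz >= 0 && resp_freq_hz >= 0, "frequencies must be >= 0")
  assert_that(participant_scale_sdlog >= 0, "participant_scale_sdlog must be >= 0")
  structure(as.list(environment()), class = "noise_spec")
}

#' Motion-artifact specification
#'
#' Spikes are short tau = 0.3 s double-exponential excursions; shifts are
#' step changes in baseline level. Rates are per minute per
#' channel-wavelength series; amplitudes on the OD scale.
#' @param spike_rate_per_min,shift_rate_per_min Event rates (1/min).
#' @param spike_amp,shift_amp Amplitudes (OD units).
#' @export
artifact_spec <- function(spike_rate_per_min = 1, spike_amp = 0.03,
                          shift_rate_per_min = 0.3, shift_amp = 0.015) {
  assert_that(spike_rate_per_min >= 0 && shift_rate_per_min >= 0,
              "artifact rates must be >= 0")
  structure(as.list(environment()), class = "artifact_spec")
}

#' Simulate a participant's look-bout timeline
#'
#' Alternates lognormal inter-look gaps and lognormal look bouts until the
#' session ends; a bout that would cross the session end is discarded.
#' Targets are drawn from the configured toy-dominant alphabet. Deterministic
#' given `(cfg$seed, participant_id)`.
#'
#' @param cfg A [sim_config()].
#' @param participant_id Participant label, e.g. `"p01"`.
#' @return A `data.frame` of look bouts with columns `participant`, `target`,
#'   `start_s`, `end_s`, sorted and non-overlapping.
#' @export
simulate_behavior <- function(cfg, participant_id) {
  stopifnot(inherits(cfg, "sim_config"))
  assert_that(cfg$session_length_s >= 0, "session length must be non-negative")
  bl <- cfg$bout_duration_lognorm
  gl <- cfg$gap_duration_lognorm
  out <- with_seed(derive_seed(cfg$seed, 1L, participant_key(participant_id)), {
    t <- 0
    starts <- ends <- numeric(0)
    repeat {
      t <- t + stats::rlnorm(1, gl[["meanlog"]], gl[["sdlog"]])
      d <- stats::rlnorm(1, bl[["meanlog"]], bl[["sdlog"]])
      if (t + d > cfg$session_length_s) break
      starts <- c(starts, t)
      ends <- c(ends, t + d)
      t <- t + d
    }
    targets <- if (length(starts)) {
      sample(names(cfg$target_weights), length(starts), replace = TRUE,
             prob = cfg$target_weights)
    } else character(0)
    data.frame(participant = rep(as.character(participant_id), length(starts)),
               target = targets, start_s = starts, end_s = ends,
               stringsAsFactors = FALSE)
  })
  out
}

#' Simulate a raw two-wavelength recording from a look-bout timeline
#'
#' Builds the latent chromophore series (double-gamma HRF convolved with a
#' boxcar starting `hrf_onset_lag_s` into every look longer than
#' `sustained_threshold_s`, added to the active channels; HbR is a scaled
#' negative copy of HbO), forward-projects it to optical density at both
#' wavelengths with the same extinction table, pathlength and DPF the
#' inverse step uses, adds physiological noise and motion artifacts, and
#' exponentiates onto the baseline intensity.
#'
#' @param cfg A [sim_config()].
#' @param bouts A look-bout `data.frame` from [simulate_behavior()] (one
#'   participant, non-overlapping).
#' @return A list with elements `recording` (class `nat_recording`) and
#'   `truth` (class `nat_truth`, carrying the latent noise-free series).
#' @export
simulate_recording <- function(cfg, bouts) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(bouts)) {
    assert_that(length(unique(bouts$participant)) == 1,
                "simulate_recording expects bouts of a single participant")
    o <- order(bouts$start_s)
    bouts <- bouts[o, , drop = FALSE]
    assert_that(all(diff(bouts$start_s) >= 0) &&
                  all(utils::head(bouts$end_s, -1) <= utils::tail(bouts$start_s, -1) + 1e-9),
                "bouts must be non-overlapping")
  }
  pid <- if (nrow(bouts)) bouts$participant[1] else "p00"
  fs <- cfg$sample_rate_hz
  n_t <- round(cfg$session_length_s * fs)
  assert_that(n_t >= 1, "session too short to hold a single sample")
  time_s <- (seq_len(n_t) - 1) / fs

  # latent concentration series (micromolar)
  stim <- numeric(n_t)
  for (i in seq_len(nrow(bouts))) {
    if (bouts$end_s[i] - bouts$start_s[i] <= cfg$sustained_threshold_s) next
    i1 <- floor((bouts$start_s[i] + cfg$hrf_onset_lag_s) * fs) + 1
    i2 <- min(floor(bouts$end_s[i] * fs), n_t)
    if (i2 >= i1 && i1 >= 1) stim[i1:i2] <- 1
  }
  kern <- hrf_kernel(fs, cfg$hrf_peak_delay_s, cfg$hrf_undershoot_delay_s,
                     cfg$hrf_undershoot_ratio)
  trace <- if (any(stim > 0)) {
    cfg$effect_amplitude_uM *
      stats::convolve(c(stim, numeric(length(kern))), rev(kern), type = "open")[seq_len(n_t)] / fs
  } else numeric(n_t)
  latent_hbo <- matrix(0, cfg$n_channels, n_t)
  if (length(cfg$active_channels)) {
    latent_hbo[cfg$active_channels, ] <-
      matrix(trace, length(cfg$active_channels), n_t, byrow = TRUE)
  }
  latent_hbr <- -cfg$hbr_ratio * latent_hbo

  # optical forward projection: Delta-OD(lambda) = (e_hbo*HbO + e_hbr*HbR)*d*DPF
  eps <- extinction_coefficients(cfg$wavelengths_nm)
  d_cm <- cfg$distance_mm / 10
  od_sig <- array(0, c(cfg$n_channels, 2, n_t))
  for (w in 1:2) {
    od_sig[, w, ] <- (eps[w, "eps_hbo"] * latent_hbo * 1e-6 +
                        eps[w, "eps_hbr"] * latent_hbr * 1e-6) * d_cm * cfg$dpf[w]
  }

  ns <- cfg$noise; ar <- cfg$artifact
  n_ch <- cfg$n_channels
  intensity <- with_seed(derive_seed(cfg$seed, 2L, participant_key(pid)), {
    scale <- if (ns$participant_scale_sdlog > 0)
      stats::rlnorm(1, -ns$participant_scale_sdlog^2 / 2, ns$participant_scale_sdlog) else 1
    out <- array(0, c(n_ch, 2, n_t))
    for (w in 1:2) {
      od_n <- matrix(0, n_ch, n_t)
      if (ns$drift_sd > 0 && n_t > 2) {
        rw <- matrix(stats::rnorm(n_ch * n_t), n_ch, n_t)
        rw <- t(apply(rw, 1, cumsum))
        rw <- rw - rowMeans(rw)
        s <- sqrt(rowSums(rw^2) / (n_t - 1))
        od_n <- od_n + rw / pmax(s, .Machine$double.eps) * ns$drift_sd
      }
      if (ns$mayer_amp > 0)
        od_n <- od_n + ns$mayer_amp *
          sin(outer(stats::runif(n_ch, 0, 2 * pi),
                    2 * pi * ns$mayer_freq_hz * time_s, `+`))
      if (ns$resp_amp > 0)
        od_n <- od_n + ns$resp_amp *
          sin(outer(stats::runif(n_ch, 0, 2 * pi),
                    2 * pi * ns$resp_freq_hz * time_s, `+`))
      if (ns$white_sd > 0)
        od_n <- od_n + matrix(stats::rnorm(n_ch * n_t, sd = ns$white_sd), n_ch, n_t)
      od_n <- od_n * scale
      if (ar$spike_amp > 0 && ar$spike_rate_per_min > 0) {
        n_spk <- stats::rpois(n_ch, ar$spike_rate_per_min * cfg$session_length_s / 60)
        for (ch in which(n_spk > 0)) {
          for (t0 in stats::runif(n_spk[ch], 0, cfg$session_length_s)) {
            od_n[ch, ] <- od_n[ch, ] + sample(c(-1, 1), 1) * ar$spike_amp *
              exp(-abs(time_s - t0) / 0.3)
          }
        }
      }
      if (ar$shift_amp > 0 && ar$shift_rate_per_min > 0) {
        n_shf <- stats::rpois(n_ch, ar$shift_rate_per_min * cfg$session_length_s / 60)
        for (ch in which(n_shf > 0)) {
          for (t0 in stats::runif(n_shf[ch], 0, cfg$session_length_s)) {
            od_n[ch, ] <- od_n[ch, ] + sample(c(-1, 1), 1) * ar$shift_amp *
              (time_s >= t0)
          }
        }
      }
      out[, w, ] <- cfg$baseline_intensity * 10^(-(od_sig[, w, ] + od_n))
    }
    out
  })

  recording <- structure(list(
    participant_id = pid,
    intensity = intensity,
    wavelengths_nm = cfg$wavelengths_nm,
    sample_rate_hz = fs,
    distance_mm = cfg$distance_mm,
    dpf = cfg$dpf,
    channel_ok = rep(TRUE, cfg$n_channels),
    time_s = time_s
  ), class = "nat_recording")
  truth <- structure(list(
    participant_id = pid,
    bouts = bouts,
    active_channels = cfg$active_channels,
    latent_hbo = latent_hbo,
    latent_hbr = latent_hbr,
    sample_rate_hz = fs
  ), class = "nat_truth")
  list(recording = recording, truth = truth)
}

#' Simulate a whole multi-participant study
#'
#' @param cfg A [sim_config()].
#' @return List with `bouts` (all participants row-bound), `recordings` and
#'   `truths` (named lists keyed by participant id).
#' @export
simulate_study <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ids <- sprintf("p%02d", seq_len(cfg$n_participants))
  bouts <- list(); recordings <- list(); truths <- list()
  for (id in ids) {
    b <- simulate_behavior(cfg, id)
    sim <- simulate_recording(cfg, if (nrow(b)) b else
      data.frame(participant = character(0), target = character(0),
                 start_s = numeric(0), end_s = numeric(0)))
    sim$recording$participant_id <- id
    sim$truth$participant_id <- id
    bouts[[id]] <- b
    recordings[[id]] <- sim$recording
    truths[[id]] <- sim$truth
  }
  list(bouts = do.call(rbind, c(bouts, list(make.row.names = FALSE))),
       recordings = recordings, truths = truths)
}

#' @export
print.nat_recording <- function(x, ...) {
  cat(sprintf("<nat_recording> %s: %d channels x 2 wavelengths (%g/%g nm) x %d samples @ %g Hz; %d/%d channels ok\n",
              x$participant_id, dim(x$intensity)[1], x$wavelengths_nm[1],
              x$wavelengths_nm[2], dim(x$intensity)[3], x$sample_rate_hz,
              sum(x$channel_ok), length(x$channel_ok)))
  invisible(x)
}
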