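# Shared fixture builders. Everything is generated in code at test time.

# small, quiet study configuration for fast end-to-end tests
quick_cfg <- function(seed = 1, n_participants = 3, session_length_s = 420,
                      noise = noise_spec(drift_sd = 0.002, mayer_amp = 5e-4,
                                         resp_amp = 5e-4, white_sd = 0.001,
                                         participant_scale_sdlog = 0),
                      artifact = artifact_spec(0, 0, 0, 0), ...) {
  sim_config(n_participants = n_participants,
             session_length_s = session_length_s,
             noise = noise, artifact = artifact, seed = seed, ...)
}

# noiseless configuration (forward model only)
clean_cfg <- function(seed = 1, ...) {
  quick_cfg(seed = seed,
            noise = noise_spec(0, 0, 0.1, 0, 0.4, 0, 0),
            artifact = artifact_spec(0, 0, 0, 0), ...)
}

# quick preprocessing settings for short test recordings
quick_pp <- function(...) preproc_params(min_data_s = 60, ...)

# a bare hb_series from explicit matrices
make_hb <- function(hbo, hbr = -hbo / 3, fs = 5, participant = "p01") {
  structure(list(
    participant_id = participant,
    hbo = hbo, hbr = hbr,
    sample_rate_hz = fs,
    channel_ok = rep(TRUE, nrow(hbo)),
    time_s = (seq_len(ncol(hbo)) - 1) / fs
  ), class = "hb_series")
}

# a recording object from an intensity array
make_recording <- function(intensity, fs = 5, distance_mm = 20,
                           wavelengths = c(763, 841), participant = "p01") {
  structure(list(
    participant_id = participant,
    intensity = intensity,
    wavelengths_nm = wavelengths,
    sample_rate_hz = fs,
    distance_mm = distance_mm,
    dpf = c(5.1, 5.1),
    channel_ok = rep(TRUE, dim(intensity)[1]),
    time_s = (seq_len(dim(intensity)[3]) - 1) / fs
  ), class = "nat_recording")
}

# bouts data frame shorthand
bouts_df <- function(start, end, target = "toy", participant = "p01") {
  data.frame(participant = participant, target = target,
             start_s = start, end_s = end, stringsAsFactors = FALSE)
}

# chain adjacency over n channels
chain_adjacency <- function(n) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) adj[i, i + 1] <- adj[i + 1, i] <- TRUE
  adj
}
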