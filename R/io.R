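# Recording and ground-truth file formats. Recordings use a documented
# long-format CSV (one sample per row) so they remain plain text and
# tool-agnostic:
#   time_s, channel, wavelength_nm, intensity

#' Write a recording to long-format CSV
#'
#' @param rec A `nat_recording`.
#' @param path Output path.
#' @export
write_recording_csv <- function(rec, path) {
  stopifnot(inherits(rec, "nat_recording"))
  n_ch <- dim(rec$intensity)[1]; n_t <- dim(rec$intensity)[3]
  dt <- data.table::data.table(
    time_s = rep(rec$time_s, times = n_ch * 2),
    channel = rep(rep(seq_len(n_ch), each = n_t), times = 2),
    wavelength_nm = rep(rec$wavelengths_nm, each = n_ch * n_t),
    intensity = c(t(rec$intensity[, 1, , drop = TRUE]),
                  t(rec$intensity[, 2, , drop = TRUE]))
  )
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read a long-format CSV recording
#'
#' @param path CSV with columns `time_s`, `channel`, `wavelength_nm`,
#'   `intensity`.
#' @param participant_id Participant label to attach.
#' @param distance_mm,dpf Optode geometry metadata (not stored in the CSV).
#' @return A `nat_recording`.
#' @export
read_recording_csv <- function(path, participant_id = "unknown",
                               distance_mm = 20, dpf = c(5.1, 5.1)) {
  dt <- data.table::fread(path)
  assert_that(all(c("time_s", "channel", "wavelength_nm", "intensity") %in%
                    names(dt)), "recording CSV is missing required columns")
  wl <- sort(unique(dt$wavelength_nm))
  assert_that(length(wl) == 2, "recording CSV must contain exactly two wavelengths")
  chans <- sort(unique(dt$channel))
  times <- sort(unique(dt$time_s))
  n_ch <- length(chans); n_t <- length(times)
  assert_that(nrow(dt) == n_ch * n_t * 2, "recording CSV is not a complete grid")
  fs <- 1 / stats::median(diff(times))
  arr <- array(NA_real_, c(n_ch, 2, n_t))
  for (w in 1:2) {
    sub <- dt[dt$wavelength_nm == wl[w], ]
    ord <- order(match(sub$channel, chans), match(sub$time_s, times))
    arr[, w, ] <- matrix(sub$intensity[ord], n_ch, n_t, byrow = TRUE)
  }
  structure(list(
    participant_id = participant_id,
    intensity = arr,
    wavelengths_nm = wl,
    sample_rate_hz = fs,
    distance_mm = distance_mm,
    dpf = dpf,
    channel_ok = rep(TRUE, n_ch),
    time_s = times
  ), class = "nat_recording")
}

#' Write simulation ground truth to a JSON sidecar
#'
#' Stores the bout table and active-channel set (the latent series are
#' reproducible from the config and are not serialised).
#'
#' @param truth A `nat_truth`.
#' @param path Output path.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "nat_truth"))
  jsonlite::write_json(list(
    participant_id = truth$participant_id,
    active_channels = truth$active_channels,
    bouts = truth$bouts
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
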