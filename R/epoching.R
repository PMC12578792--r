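#' Epoching parameters
#'
#' Defines the attention-phase active-baseline block geometry: each event
#' contributes an 18-s block made of a 3-s pre-stimulus baseline beginning
#' 3 s before the (shifted) onset and a 15-s post-stimulus window. The onset
#' shift moves the analysis start into the look so the baseline captures the
#' pre-attention/orienting phases (+3 s protocol; 0, +6 and random are the
#' validation conditions).
#'
#' @param shift_s Onset shift in seconds, or the string `"random"` (per-event
#'   random sign, magnitude uniform on `random_shift_range_s`).
#' @param baseline_s Baseline length (s) preceding the shifted onset.
#' @param block_s Post-stimulus block length (s).
#' @param min_isi_s Events are dropped when the gap between the previous
#'   event's block end and their own baseline start is below this (s).
#' @param peak_halfwidth_s Half-width (s) of the averaging window around the
#'   per-channel peak.
#' @param activation_window_s Window (s, relative to shifted onset) searched
#'   for the peak; defaults to the full post-stimulus block.
#' @param random_shift_range_s Magnitude range of random shifts (s).
#' @param peak_mode How the per-channel peak is located inside the
#'   activation window. `"abs"` (default) takes the largest absolute
#'   deflection and keeps its sign, so the statistic is sign-symmetric under
#'   the null; `"directional"` takes the maximum for HbO and the minimum for
#'   HbR, which carries a positive selection bias on null data (see the
#'   methods vignette).
#' @export
epoch_params <- function(shift_s = 3, baseline_s = 3, block_s = 15,
                         min_isi_s = 5, peak_halfwidth_s = 2.5,
                         activation_window_s = c(0, 15),
                         random_shift_range_s = c(15, 30),
                         peak_mode = c("abs", "directional")) {
  peak_mode <- match.arg(peak_mode)
  assert_that(baseline_s > 0 && block_s > 0, "window lengths must be positive")
  assert_that(peak_halfwidth_s <= block_s / 2,
              "peak_halfwidth_s must not exceed half the block")
  assert_that(activation_window_s[1] >= 0 && activation_window_s[2] <= block_s &&
                activation_window_s[1] < activation_window_s[2],
              "activation window must lie within [0, block_s]")
  assert_that(is.numeric(shift_s) || identical(shift_s, "random"),
              "shift_s must be numeric or 'random'")
  assert_that(min_isi_s >= 0, "min_isi_s must be >= 0")
  structure(as.list(environment()), class = "epoch_params")
}

#' Apply the onset shift to attention events
#'
#' Sets `shift_s` and `onset_s = look_onset_s + shift_s` per event. In random
#' mode each event independently receives a shift of random sign with
#' magnitude uniform on `params$random_shift_range_s`, reproducibly from
#' `seed`.
#'
#' @param events Event `data.frame` from [extract_events()].
#' @param params An [epoch_params()].
#' @param seed Seed for random mode.
#' @return The events with `shift_s`/`onset_s` updated.
#' @export
apply_shift <- function(events, params = epoch_params(), seed = 1L) {
  stopifnot(inherits(params, "epoch_params"))
  n <- nrow(events)
  if (identical(params$shift_s, "random")) {
    r <- params$random_shift_range_s
    events$shift_s <- with_seed(derive_seed(seed, 3L), {
      sample(c(-1, 1), n, replace = TRUE) * stats::runif(n, r[1], r[2])
    })
  } else {
    events$shift_s <- rep(params$shift_s, n)
  }
  events$onset_s <- events$look_onset_s + events$shift_s
  events
}

#' Exclude events with short interstimulus intervals
#'
#' An event is dropped when the gap between the previous kept event's block
#' end (`onset + block_s`) and its own baseline start (`onset - baseline_s`)
#' is shorter than `min_isi_s`, preventing the delayed hemodynamic response
#' of one event from bleeding into the next event's baseline.
#'
#' @param events Shifted event `data.frame` (see [apply_shift()]).
#' @param params An [epoch_params()].
#' @return The surviving events.
#' @export
exclude_short_isi <- function(events, params = epoch_params()) {
  stopifnot(inherits(params, "epoch_params"))
  if (!nrow(events)) return(events)
  keep <- logical(nrow(events))
  for (p in unique(events$participant)) {
    idx <- which(events$participant == p)
    idx <- idx[order(events$onset_s[idx])]
    last_end <- -Inf
    for (i in idx) {
      if (events$onset_s[i] - params$baseline_s - last_end >= params$min_isi_s) {
        keep[i] <- TRUE
        last_end <- events$onset_s[i] + params$block_s
      }
    }
  }
  out <- events[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract baseline-corrected blocks around shifted onsets
#'
#' Each event yields the segment `[onset - baseline_s, onset + block_s)`
#' (half-open, onset mapped to the nearest sample; 90 samples at 5 Hz with
#' defaults), baseline-corrected by subtracting the mean of the baseline
#' samples per channel and chromophore. Segments truncated by the recording
#' edges are discarded and counted, not errored.
#'
#' @param hb An `hb_series`.
#' @param events Event `data.frame` (rows for other participants are
#'   ignored).
#' @param params An [epoch_params()].
#' @return An object of class `attn_blocks`: arrays `hbo`/`hbr` of dimension
#'   blocks x channels x time, the relative time axis `rel_time`, and
#'   `n_discarded`.
#' @export
extract_blocks <- function(hb, events, params = epoch_params()) {
  stopifnot(inherits(hb, "hb_series"), inherits(params, "epoch_params"))
  events <- events[events$participant == hb$participant_id, , drop = FALSE]
  fs <- hb$sample_rate_hz
  n_t <- ncol(hb$hbo)
  nb0 <- round(params$baseline_s * fs)
  n_b <- round((params$baseline_s + params$block_s) * fs)
  rel_time <- (seq_len(n_b) - 1) / fs - params$baseline_s
  n_ch <- nrow(hb$hbo)
  kept <- list(); n_disc <- 0L
  for (i in seq_len(nrow(events))) {
    onset_idx <- round(events$onset_s[i] * fs) + 1L
    i0 <- onset_idx - nb0
    i1 <- i0 + n_b - 1L
    if (i0 < 1L || i1 > n_t) { n_disc <- n_disc + 1L; next }
    kept[[length(kept) + 1L]] <- i0:i1
  }
  hbo <- array(NA_real_, c(length(kept), n_ch, n_b))
  hbr <- hbo
  for (b in seq_along(kept)) {
    seg_o <- hb$hbo[, kept[[b]], drop = FALSE]
    seg_r <- hb$hbr[, kept[[b]], drop = FALSE]
    base_o <- rowMeans(seg_o[, seq_len(nb0), drop = FALSE])
    base_r <- rowMeans(seg_r[, seq_len(nb0), drop = FALSE])
    hbo[b, , ] <- seg_o - base_o
    hbr[b, , ] <- seg_r - base_r
  }
  structure(list(
    participant_id = hb$participant_id,
    hbo = hbo, hbr = hbr,
    rel_time = rel_time,
    sample_rate_hz = fs,
    channel_ok = hb$channel_ok,
    n_discarded = n_disc
  ), class = "attn_blocks")
}

#' Average blocks within a participant
#'
#' @param blocks An `attn_blocks`.
#' @return An `attn_blockavg` with channel x time mean `hbo`/`hbr` and the
#'   contributing block count.
#' @export
block_average <- function(blocks) {
  stopifnot(inherits(blocks, "attn_blocks"))
  nb <- dim(blocks$hbo)[1]
  avg <- function(a) {
    if (nb == 0) matrix(NA_real_, dim(a)[2], dim(a)[3])
    else apply(a, c(2, 3), mean)
  }
  structure(list(
    participant_id = blocks$participant_id,
    hbo = avg(blocks$hbo), hbr = avg(blocks$hbr),
    rel_time = blocks$rel_time,
    sample_rate_hz = blocks$sample_rate_hz,
    channel_ok = blocks$channel_ok,
    n_blocks = nb
  ), class = "attn_blockavg")
}

# index of the peak sample inside the activation window;
# direction: "abs" (largest |v|), "max", or "min"
peak_index <- function(v, rel_time, params, direction) {
  act <- rel_time >= params$activation_window_s[1] &
    rel_time < params$activation_window_s[2]
  if (!any(act) || all(is.na(v[act]))) return(NA_integer_)
  iact <- which(act)
  iact[switch(direction,
              abs = which.max(abs(v[iact])),
              max = which.max(v[iact]),
              min = which.min(v[iact]))]
}

# peak-window statistic of one trace: locate the peak inside the activation
# window, average over +/- peak_halfwidth_s clipped to the block
peak_response_trace <- function(v, rel_time, params, direction = "abs") {
  pk <- peak_index(v, rel_time, params, direction)
  if (is.na(pk)) return(NA_real_)
  win <- abs(rel_time - rel_time[pk]) <= params$peak_halfwidth_s + 1e-9
  mean(v[win], na.rm = TRUE)
}

# latency (s, relative to shifted onset) of the peak
peak_latency_trace <- function(v, rel_time, params, direction = "abs") {
  pk <- peak_index(v, rel_time, params, direction)
  if (is.na(pk)) return(NA_real_)
  rel_time[pk]
}

# resolve the peak-search direction from the params and chromophore
peak_direction <- function(params, chromophore) {
  if (identical(params$peak_mode, "directional")) {
    if (chromophore == "hbo") "max" else "min"
  } else "abs"
}

#' Peak-window mean responses per participant and channel
#'
#' For every participant the blocks are averaged, the per-channel peak
#' (maximum for HbO, minimum for HbR) is located inside the activation
#' window, and the block average is averaged over a window of
#' `+/- peak_halfwidth_s` around the peak (clipped to the block). Channels
#' with no usable block are returned as missing, never zero.
#'
#' @param blocks_list A list of `attn_blocks` (one per participant) or a
#'   single `attn_blocks`.
#' @param params An [epoch_params()].
#' @param chromophore `"hbo"` or `"hbr"`.
#' @return A `data.frame` with `participant`, `channel`, `response` (uM) and
#'   `n_blocks`.
#' @export
peak_window_mean <- function(blocks_list, params = epoch_params(),
                             chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  if (inherits(blocks_list, "attn_blocks")) blocks_list <- list(blocks_list)
  direction <- peak_direction(params, chromophore)
  out <- lapply(blocks_list, function(b) {
    avg <- if (inherits(b, "attn_blockavg")) b else block_average(b)
    if (avg$n_blocks == 0) return(NULL)
    tr <- avg[[chromophore]]
    resp <- vapply(seq_len(nrow(tr)), function(ch) {
      if (!avg$channel_ok[ch]) return(NA_real_)
      peak_response_trace(tr[ch, ], avg$rel_time, params, direction)
    }, numeric(1))
    data.frame(participant = avg$participant_id,
               channel = seq_len(nrow(tr)),
               response = resp,
               n_blocks = avg$n_blocks,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(participant = character(0), channel = integer(0),
                      response = numeric(0), n_blocks = integer(0))
  rownames(out) <- NULL
  out[!is.na(out$response), , drop = FALSE]
}

#' Arrange a response table as a participants x channels matrix
#'
#' @param responses Output of [peak_window_mean()].
#' @param n_channels Number of channels (columns).
#' @return Numeric matrix with `NA` where a participant-channel response is
#'   missing; participant ids as row names.
#' @export
response_matrix <- function(responses, n_channels) {
  ids <- unique(responses$participant)
  m <- matrix(NA_real_, length(ids), n_channels,
              dimnames = list(ids, NULL))
  m[cbind(match(responses$participant, ids), responses$channel)] <- responses$response
  m
}

#' Per-channel peak latency of a block average
#'
#' @param blockavg An `attn_blockavg` (or `attn_blocks`, averaged first).
#' @param params An [epoch_params()].
#' @param chromophore `"hbo"` or `"hbr"`.
#' @return Numeric vector of latencies (s after shifted onset) per channel.
#' @export
peak_latency <- function(blockavg, params = epoch_params(),
                         chromophore = c("hbo", "hbr")) {
  chromophore <- match.arg(chromophore)
  if (inherits(blockavg, "attn_blocks")) blockavg <- block_average(blockavg)
  direction <- peak_direction(params, chromophore)
  tr <- blockavg[[chromophore]]
  vapply(seq_len(nrow(tr)), function(ch) {
    if (!blockavg$channel_ok[ch]) return(NA_real_)
    peak_latency_trace(tr[ch, ], blockavg$rel_time, params, direction)
  }, numeric(1))
}

#' Grand average of participant block averages
#'
#' @param blockavgs List of `attn_blockavg` (or `attn_blocks`).
#' @return An `attn_blockavg` averaging participants with equal weight.
#' @export
grand_average <- function(blockavgs) {
  blockavgs <- lapply(blockavgs, function(b)
    if (inherits(b, "attn_blocks")) block_average(b) else b)
  blockavgs <- Filter(function(b) b$n_blocks > 0, blockavgs)
  assert_that(length(blockavgs) > 0, "no participant contributed blocks")
  hbo <- Reduce(`+`, lapply(blockavgs, `[[`, "hbo")) / length(blockavgs)
  hbr <- Reduce(`+`, lapply(blockavgs, `[[`, "hbr")) / length(blockavgs)
  out <- blockavgs[[1]]
  out$participant_id <- "grand"
  out$hbo <- hbo; out$hbr <- hbr
  out$n_blocks <- sum(vapply(blockavgs, `[[`, numeric(1), "n_blocks"))
  out$channel_ok <- Reduce(`&`, lapply(blockavgs, `[[`, "channel_ok"))
  out
}
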