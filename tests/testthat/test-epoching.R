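events_df <- function(onsets, participant = "p01", duration = 10) {
  data.frame(participant = participant, target = "toy",
             look_onset_s = onsets, duration_s = duration,
             shift_s = 0, onset_s = onsets, stringsAsFactors = FALSE)
}

test_that("onset shifts are applied per protocol and reproducibly at random", {
  ev <- events_df(100)
  expect_equal(apply_shift(ev, epoch_params(shift_s = 3))$onset_s, 103)
  expect_equal(apply_shift(ev, epoch_params(shift_s = 0)), ev)

  evn <- events_df(seq(50, 950, by = 50))
  p <- epoch_params(shift_s = "random")
  r1 <- apply_shift(evn, p, seed = 9)
  r2 <- apply_shift(evn, p, seed = 9)
  expect_identical(r1, r2)
  expect_true(all(abs(r1$shift_s) >= 15 & abs(r1$shift_s) <= 30))
  expect_true(any(r1$shift_s < 0) && any(r1$shift_s > 0))
  expect_false(identical(r1$shift_s, apply_shift(evn, p, seed = 10)$shift_s))
})

test_that("short interstimulus intervals drop the later event", {
  p <- epoch_params()
  # two events 60 s apart: gap = 60 - 15 - 3 = 42 s, both kept
  expect_equal(nrow(exclude_short_isi(events_df(c(100, 160)), p)), 2)
  # gap of 3 s between block end and next baseline start: second dropped
  # onset2 = onset1 + 15 + 3 + 3 = onset1 + 21
  kept <- exclude_short_isi(events_df(c(100, 121)), p)
  expect_equal(kept$onset_s, 100)
  # exactly 5 s gap is kept (rule drops strictly shorter gaps)
  expect_equal(nrow(exclude_short_isi(events_df(c(100, 123)), p)), 2)
})

test_that("ISI exclusion matches a brute-force sequential rule", {
  brute <- function(onsets, baseline = 3, block = 15, min_isi = 5) {
    onsets <- sort(onsets)
    kept <- c()
    last_end <- -Inf
    for (o in onsets) {
      if ((o - baseline) - last_end >= min_isi) {
        kept <- c(kept, o)
        last_end <- o + block
      }
    }
    kept
  }
  set.seed(11)
  for (rep in 1:500) {
    onsets <- sort(runif(sample(1:12, 1), 0, 600))
    out <- exclude_short_isi(events_df(onsets), epoch_params())
    expect_equal(out$onset_s, brute(onsets))
  }
})

test_that("blocks have the stated geometry and baseline correction", {
  n_ch <- 3; n_t <- 1500
  hb <- make_hb(matrix(2.5, n_ch, n_t))
  ev <- events_df(c(100, 200))
  bl <- extract_blocks(hb, ev, epoch_params())
  # (3 + 15) s at 5 Hz, half-open -> 90 samples
  expect_equal(dim(bl$hbo), c(2, 3, 90))
  expect_equal(bl$rel_time[1], -3)
  expect_equal(bl$rel_time[90], 14.8)
  # constant series -> exactly zero after baseline correction
  expect_equal(max(abs(bl$hbo)), 0)
  expect_equal(max(abs(bl$hbr)), 0)

  # events beyond the recording edge are discarded and counted, not errors
  bl2 <- extract_blocks(hb, events_df(c(100, 295)), epoch_params())
  expect_equal(dim(bl2$hbo)[1], 1)
  expect_equal(bl2$n_discarded, 1)

  # baseline correction is idempotent
  seg <- bl$hbo[1, , ]
  base <- rowMeans(seg[, 1:15])
  expect_equal(seg - base, seg)
})

test_that("the peak-window mean reproduces closed-form values", {
  p <- epoch_params()
  fs <- 5
  rel <- seq(-3, 14.8, by = 1 / fs)
  # constant block average -> response equals the constant
  avg <- structure(list(participant_id = "p01",
                        hbo = matrix(0.7, 1, length(rel)),
                        hbr = matrix(-0.2, 1, length(rel)),
                        rel_time = rel, sample_rate_hz = fs,
                        channel_ok = TRUE, n_blocks = 4),
                   class = "attn_blockavg")
  r <- peak_window_mean(list(avg), p, "hbo")
  expect_equal(r$response, 0.7)

  # triangular pulse peaking at 7 s, amplitude 1, half-width 5 s:
  # mean over [4.5, 9.5] s = 0.75 (continuous); the sampled grid gives the
  # same value to < 1e-3
  tri <- pmax(0, 1 - abs(rel - 7) / 5)
  avg$hbo <- matrix(tri, 1)
  win <- abs(rel - 7) <= 2.5 + 1e-9
  expect_equal(peak_window_mean(list(avg), p, "hbo")$response,
               mean(tri[win]))
  expect_equal(peak_window_mean(list(avg), p, "hbo")$response, 0.75,
               tolerance = 1e-3)

  # negative-going pulse: peak found at the minimum, response keeps its sign
  avg$hbr <- matrix(-tri, 1)
  expect_equal(peak_window_mean(list(avg), p, "hbr")$response, -0.75,
               tolerance = 1e-3)
  expect_equal(peak_latency(avg, p, "hbr"), 7)

  # directional mode agrees on genuinely positive responses
  avg$hbo <- matrix(tri, 1)
  pd <- epoch_params(peak_mode = "directional")
  expect_equal(peak_window_mean(list(avg), pd, "hbo")$response,
               peak_window_mean(list(avg), p, "hbo")$response)

  # channels without blocks are missing, not zero
  avg0 <- avg; avg0$n_blocks <- 0
  expect_equal(nrow(peak_window_mean(list(avg0), p, "hbo")), 0)
})

test_that("responses are invariant to a rigid time translation", {
  cfg <- quick_cfg(seed = 8, n_participants = 1, session_length_s = 600)
  sim <- simulate_recording(cfg, simulate_behavior(cfg, "p01"))
  hb <- preprocess(sim$recording, quick_pp(do_bandpass = FALSE,
                                           do_wavelet = FALSE,
                                           do_spline = FALSE))
  ev <- extract_events(merge_bouts(simulate_behavior(cfg, "p01")))
  ev <- apply_shift(ev, epoch_params())
  ev <- exclude_short_isi(ev, epoch_params())
  # drop events too close to the edges so both alignments keep all blocks
  ev <- ev[ev$onset_s > 40 & ev$onset_s < 540, ]
  delta <- 4  # whole seconds -> whole samples at 5 Hz
  hb2 <- hb
  n <- ncol(hb$hbo); k <- delta * 5
  hb2$hbo <- cbind(matrix(0, nrow(hb$hbo), k), hb$hbo[, 1:(n - k)])
  hb2$hbr <- cbind(matrix(0, nrow(hb$hbr), k), hb$hbr[, 1:(n - k)])
  ev2 <- ev; ev2$onset_s <- ev$onset_s + delta
  r1 <- peak_window_mean(list(extract_blocks(hb, ev)), epoch_params())
  r2 <- peak_window_mean(list(extract_blocks(hb2, ev2)), epoch_params())
  expect_equal(r1$response, r2$response, tolerance = 1e-10)
})

test_that("active channels rise within the block and shifting moves latency", {
  cfg <- clean_cfg(seed = 2, n_participants = 1, session_length_s = 1200)
  b <- simulate_behavior(cfg, "p01")
  sim <- simulate_recording(cfg, b)
  hb <- preprocess(sim$recording, quick_pp(do_bandpass = FALSE,
                                           do_wavelet = FALSE,
                                           do_spline = FALSE))
  ev0 <- extract_events(merge_bouts(b))
  p3 <- epoch_params(shift_s = 3); p0 <- epoch_params(shift_s = 0)
  ev3 <- exclude_short_isi(apply_shift(ev0, p3), p3)
  bl3 <- extract_blocks(hb, ev3, p3)
  avg3 <- block_average(bl3)
  ch <- cfg$active_channels[1]
  # block average positive over the activation window
  expect_gt(mean(avg3$hbo[ch, avg3$rel_time >= 0]), 0)
  # response is detectable (over half of peak) 5-8 s after the shifted
  # onset, with the peak itself later in the block
  peak_val <- max(avg3$hbo[ch, ])
  expect_gt(max(avg3$hbo[ch, avg3$rel_time >= 5 & avg3$rel_time <= 8]),
            0.5 * peak_val)
  lat3 <- peak_latency(avg3, p3)[ch]
  expect_true(lat3 > 4 && lat3 < 15)

  evA <- exclude_short_isi(apply_shift(ev0, p0), p0)
  common <- intersect(round(evA$look_onset_s, 3), round(ev3$look_onset_s, 3))
  evA <- evA[round(evA$look_onset_s, 3) %in% common, ]
  evB <- ev3[round(ev3$look_onset_s, 3) %in% common, ]
  avg0 <- block_average(extract_blocks(hb, evA, p0))
  avgB <- block_average(extract_blocks(hb, evB, p3))
  lat0 <- peak_latency(avg0, p0)[ch]
  latB <- peak_latency(avgB, p3)[ch]
  # +0 peak latency exceeds +3 latency by the 3-s shift (within one sample)
  expect_equal(lat0 - latB, 3, tolerance = 0.2 + 1e-9)
})
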