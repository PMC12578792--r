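flat_recording <- function(level = 5, n_ch = 44, n_t = 1600) {
  make_recording(array(level, c(n_ch, 2, n_t)))
}

test_that("channels are pruned on intensity bounds; bad recordings rejected", {
  pp <- quick_pp()
  rec <- flat_recording(5)
  expect_true(all(prune_channels(rec, pp)$channel_ok))

  rec$intensity[7, , ] <- 1.0  # below the lower bound of 2
  pruned <- prune_channels(rec, pp)
  expect_false(pruned$channel_ok[7])
  expect_equal(sum(!pruned$channel_ok), 1)

  # 23 of 44 bad channels crosses the 50% exclusion rule
  rec2 <- flat_recording(5)
  rec2$intensity[1:23, , ] <- 12
  expect_error(prune_channels(rec2, pp),
               class = "natfnirs_recording_rejected")

  # too-short recordings are rejected outright, same condition class
  rec3 <- flat_recording(5, n_t = 200)
  expect_error(prune_channels(rec3, preproc_params(min_data_s = 300)),
               class = "natfnirs_recording_rejected")

  # distance outside the source-detector range prunes everything -> reject
  rec4 <- flat_recording(5)
  rec4$distance_mm <- 60
  expect_error(prune_channels(rec4, pp),
               class = "natfnirs_recording_rejected")
})

test_that("optical density follows the log identity", {
  rec <- flat_recording(5, n_ch = 2, n_t = 500)
  od <- intensity_to_od(rec)
  expect_equal(max(abs(od$od)), 0)

  # one sample at a tenth of the channel mean gives OD = 1 there
  rec2 <- flat_recording(5, n_ch = 1, n_t = 1000)
  rec2$intensity[1, 1, 100] <- mean(rec2$intensity[1, 1, ]) / 10
  od2 <- intensity_to_od(rec2)
  ibar <- mean(rec2$intensity[1, 1, ])
  expect_equal(od2$od[1, 1, 100], -log10(rec2$intensity[1, 1, 100] / ibar))

  rec3 <- flat_recording(5, n_ch = 2, n_t = 400)
  rec3$intensity[2, 2, 7] <- 0
  expect_error(intensity_to_od(rec3), "non-positive")
})

test_that("wavelet correction attenuates spikes but preserves clean signal", {
  n_t <- 1500
  t <- (seq_len(n_t) - 1) / 5
  base <- 0.01 * sin(2 * pi * 0.05 * t)
  rec <- flat_recording(5, n_ch = 2, n_t = n_t)
  rec$intensity[1, 1, ] <- 5 * 10^(-base)
  od <- intensity_to_od(rec)
  clean <- od$od[1, 1, ]
  spike <- 10 * sd(clean)
  od$od[1, 1, 700] <- od$od[1, 1, 700] + spike

  out <- wavelet_correct(od, 0.8, 4)
  expect_lt(abs(out$od[1, 1, 700] - clean[700]), 0.2 * spike)
  expect_lt(sqrt(mean((wavelet_correct(intensity_to_od(rec), 0.8, 4)$od[1, 1, ] -
                         clean)^2)) / sd(clean), 0.05)
  # untouched zero channel stays zero
  expect_equal(max(abs(out$od[2, , ])), 0)
})

test_that("spline correction removes masked step artifacts and nothing else", {
  n_t <- 1000
  set.seed(2)
  x <- 0.002 * rnorm(n_t)
  A <- 0.05
  x2 <- x + A * (seq_len(n_t) >= 500)           # persistent baseline step
  od <- structure(list(participant_id = "p", od = array(0, c(1, 2, n_t)),
                       wavelengths_nm = c(763, 841), sample_rate_hz = 5,
                       distance_mm = 20, dpf = c(5.1, 5.1),
                       channel_ok = TRUE, time_s = (1:n_t) / 5),
                  class = "nat_od")
  od$od[1, 1, ] <- x2
  od$od[1, 2, ] <- x2

  # empty mask is the identity
  expect_equal(spline_correct(od, 0.99, matrix(FALSE, 1, n_t)), od)

  mask <- matrix(FALSE, 1, n_t)
  mask[1, 480:520] <- TRUE
  out <- spline_correct(od, 0.99, mask)
  resid_step <- mean(out$od[1, 1, 600:900]) - mean(out$od[1, 1, 100:400])
  expect_lt(abs(resid_step), 0.2 * A)

  # locality: samples outside the mask change only by a constant level shift
  pre <- out$od[1, 1, 1:479] - x2[1:479]
  post <- out$od[1, 1, 521:n_t] - x2[521:n_t]
  expect_lt(diff(range(pre)), 1e-9)
  expect_lt(diff(range(post)), 1e-9)
})

test_that("the moving-SD detector finds injected motion segments", {
  n_t <- 2000
  set.seed(5)
  od <- structure(list(participant_id = "p", od = array(0, c(2, 2, n_t)),
                       wavelengths_nm = c(763, 841), sample_rate_hz = 5,
                       distance_mm = 20, dpf = c(5.1, 5.1),
                       channel_ok = c(TRUE, TRUE), time_s = (1:n_t) / 5),
                  class = "nat_od")
  od$od[1, 1, ] <- 0.002 * rnorm(n_t)
  od$od[1, 1, 1000:1004] <- od$od[1, 1, 1000:1004] + 0.08
  od$od[2, 1, ] <- 0.002 * rnorm(n_t)
  mask <- detect_motion(od, 1, 5)
  expect_true(all(mask[1, 1000:1004]))
  expect_false(any(mask[2, ]))
})

test_that("band-pass response: DC removed, pass-band kept, stop-band crushed", {
  n_t <- 6000
  fs <- 5
  t <- (seq_len(n_t) - 1) / fs
  od0 <- structure(list(participant_id = "p", od = array(0, c(1, 2, n_t)),
                        wavelengths_nm = c(763, 841), sample_rate_hz = fs,
                        distance_mm = 20, dpf = c(5.1, 5.1),
                        channel_ok = TRUE, time_s = t),
                   class = "nat_od")
  gain <- function(f) {
    od <- od0
    od$od[1, 1, ] <- if (f == 0) 1 else sin(2 * pi * f * t)
    y <- bandpass(od)$od[1, 1, ]
    max(abs(y[1500:4500]))
  }
  expect_lt(gain(0), 1e-3)
  expect_gt(gain(0.1), 0.95)
  expect_lt(gain(0.002), 0.1)
  expect_error(bandpass(od0, 1, 3), "infeasible")
})

test_that("matrix filtering is numerically identical to signal::filtfilt", {
  set.seed(3)
  bf <- signal::butter(3, 0.004, type = "high")
  x <- cumsum(rnorm(3000))
  expect_equal(natfnirs:::filtfilt_mat(bf$b, bf$a, cbind(x))[, 1],
               signal::filtfilt(bf, x), tolerance = 1e-9)
})

test_that("Beer-Lambert inversion is a linear round trip", {
  n_t <- 400
  eps <- extinction_coefficients(c(763, 841))
  hbo <- matrix(sin(2 * pi * 0.03 * (1:n_t) / 5), 1) * 0.4   # uM
  hbr <- -hbo / 3
  d_cm <- 2; dpf <- c(5.1, 5.1)
  od <- structure(list(participant_id = "p", od = array(0, c(1, 2, n_t)),
                       wavelengths_nm = c(763, 841), sample_rate_hz = 5,
                       distance_mm = 20, dpf = dpf,
                       channel_ok = TRUE, time_s = (1:n_t) / 5),
                  class = "nat_od")
  for (w in 1:2) {
    od$od[1, w, ] <- (eps[w, "eps_hbo"] * hbo * 1e-6 +
                        eps[w, "eps_hbr"] * hbr * 1e-6) * d_cm * dpf[w]
  }
  hb <- mbll(od)
  expect_equal(hb$hbo[1, ], hbo[1, ], tolerance = 1e-9)
  expect_equal(hb$hbr[1, ], hbr[1, ], tolerance = 1e-9)

  # zero OD -> zero concentrations; doubling OD doubles concentrations
  od0 <- od; od0$od[] <- 0
  expect_equal(max(abs(mbll(od0)$hbo)), 0)
  od2 <- od; od2$od <- od$od * 2
  expect_equal(mbll(od2)$hbo, hb$hbo * 2, tolerance = 1e-12)

  # singular extinction matrix is refused
  bad <- eps; bad[2, ] <- bad[1, ]
  expect_error(mbll(od, extinction = bad), "singular")
})

test_that("no preprocessing stage un-prunes a channel", {
  cfg <- quick_cfg(seed = 4, n_participants = 1)
  sim <- simulate_recording(cfg, simulate_behavior(cfg, "p01"))
  rec <- sim$recording
  rec$intensity[5, , ] <- rec$intensity[5, , ] / 10  # force pruning
  rec <- prune_channels(rec, quick_pp())
  expect_false(rec$channel_ok[5])
  hb <- mbll(bandpass(wavelet_correct(intensity_to_od(rec))))
  expect_false(hb$channel_ok[5])
  expect_true(all(is.na(hb$hbo[5, ])))
})

test_that("noise-free synthetic data round-trips through the chain within 1%", {
  cfg <- clean_cfg(seed = 6, n_participants = 1, session_length_s = 600)
  b <- simulate_behavior(cfg, "p01")
  sim <- simulate_recording(cfg, b)
  hb <- preprocess(sim$recording,
                   quick_pp(do_wavelet = FALSE, do_spline = FALSE,
                            do_bandpass = FALSE))
  for (ch in cfg$active_channels) {
    lat <- sim$truth$latent_hbo[ch, ]
    latc <- lat - mean(lat)
    expect_lt(sqrt(mean((hb$hbo[ch, ] - latc)^2)) / sqrt(mean(latc^2)), 0.01)
  }
  # inactive channel recovers (centred) zero
  expect_lt(max(abs(hb$hbo[20, ])), 1e-6)
})
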