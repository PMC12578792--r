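# construct a sample with exactly the requested mean and sd
exact_sample <- function(n, mean, sd, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  x <- (x - mean(x)) / stats::sd(x)
  x * sd + mean
}

test_that("published ROI summary table closes arithmetically", {
  ref <- read.delim(system.file("extdata", "roi_hbo_reference.tsv",
                                package = "natfnirs"))
  for (i in seq_len(nrow(ref))) {
    n <- ref$df[i] + 1
    x <- exact_sample(n, ref$mean[i], ref$sd[i], seed = i)
    r <- one_sample_t(x, "greater")
    expect_equal(round(r$t, 3), ref$t[i])
    expect_equal(round(r$p, 3), ref$p[i])
    expect_equal(round(cohens_d(x), 2), ref$d[i])
    expect_equal(r$df, ref$df[i])
  }
})

test_that("t statistic and p agree with stats::t.test and quadrature", {
  set.seed(21)
  for (rep in 1:20) {
    x <- rnorm(sample(3:15, 1), mean = runif(1, -1, 1))
    r <- one_sample_t(x, "greater")
    tt <- t.test(x, alternative = "greater")
    expect_equal(r$t, unname(tt$statistic))
    expect_equal(r$p, tt$p.value)
    # independent quadrature of the t density
    pq <- integrate(function(u) dt(u, r$df), r$t, Inf)$value
    expect_equal(r$p, pq, tolerance = 1e-6)
  }
  # symmetric values give t = 0, p = 1/2
  r0 <- one_sample_t(c(-2, -1, 1, 2), "greater")
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 0.5)
  expect_error(one_sample_t(rep(1, 5)), "zero standard deviation")
  expect_error(one_sample_t(3), "two observations")
})

test_that("Cohen's d satisfies d = t/sqrt(n)", {
  set.seed(5)
  for (rep in 1:10) {
    x <- rnorm(sample(4:20, 1), mean = 0.3)
    r <- one_sample_t(x, "greater")
    expect_equal(cohens_d(x), r$t / sqrt(r$n))
  }
  expect_error(cohens_d(rep(2, 4)), "zero standard deviation")
})

test_that("post hoc power is alpha at zero effect, monotone, and matches Monte Carlo", {
  expect_equal(posthoc_power(0, 11, 0.05, "greater"), 0.05, tolerance = 1e-12)

  grid_d <- seq(0, 1.5, by = 0.25)
  pw <- vapply(grid_d, posthoc_power, numeric(1), n = 11)
  expect_true(all(diff(pw) > 0))
  pw_n <- vapply(c(4, 8, 16, 32), function(n) posthoc_power(0.5, n), numeric(1))
  expect_true(all(diff(pw_n) > 0))

  # Monte-Carlo oracle: 1e5 simulated experiments at d = 0.68, n = 11
  set.seed(99)
  d <- 0.68; n <- 11; B <- 1e5
  x <- matrix(rnorm(B * n, mean = d), B, n)
  m <- rowMeans(x)
  s <- sqrt(rowSums((x - m)^2) / (n - 1))
  tstat <- m / (s / sqrt(n))
  mc <- mean(tstat > qt(0.95, n - 1))
  expect_equal(posthoc_power(d, n, 0.05, "greater"), mc, tolerance = 0.01)

  # decrease-direction power mirrors the increase direction
  expect_equal(posthoc_power(-0.5, 11, 0.05, "less"),
               posthoc_power(0.5, 11, 0.05, "greater"))
})

test_that("FDR adjustment follows the BH step-up (and fixed-pi0 Storey mode)", {
  expect_equal(fdr_adjust(0.03), 0.03)
  # hand-computed step-up: p (0.01 0.02 0.03 0.04) * 4/(1:4), cummin from top
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- c(0.001, 0.2, 0.013, 0.8, 0.04)
  q <- fdr_adjust(p)
  expect_equal(order(q), order(p))         # ordering preserved
  expect_equal(q, p.adjust(p, "BH"))
  expect_equal(fdr_adjust(p, "storey", pi0 = 0.5), pmin(1, 0.5 * p.adjust(p, "BH")))
  expect_equal(fdr_adjust(numeric(0)), numeric(0))
})

test_that("ROI aggregation averages available channels and drops empty participants", {
  resp <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(paste0("p", 1:5), NULL))
  roi <- list(a = 1L, b = c(2L, 3L, 4L))
  agg <- roi_aggregate(resp, roi)
  expect_equal(agg[, "a"], resp[, 1])      # single-channel ROI is the identity
  expect_equal(agg[, "b"], rowMeans(resp[, 2:4]))

  # a participant missing all of one ROI's channels is dropped there only
  resp[2, 2:4] <- NA
  agg2 <- roi_aggregate(resp, roi)
  expect_true(is.na(agg2[2, "b"]) && !is.na(agg2[2, "a"]))
  rs <- roi_stats(resp, roi)
  expect_equal(rs$df, c(4, 3))             # df heterogeneity across ROIs

  # brute-force oracle over random missingness masks
  set.seed(31)
  for (rep in 1:50) {
    m <- matrix(rnorm(4 * 8), 4, 8)
    m[sample(length(m), 6)] <- NA
    roi2 <- list(x = 1:3, y = 4:8)
    agg3 <- roi_aggregate(m, roi2)
    for (i in 1:4) for (r in names(roi2)) {
      v <- m[i, roi2[[r]]]
      ref <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
      expect_equal(unname(agg3[i, r]), ref)
    }
  }
  expect_error(roi_aggregate(resp, list()), "empty")
})

test_that("channel-wise testing holds its level on null data and ranks true effects", {
  set.seed(77)
  hits <- 0; total <- 0
  for (rep in 1:200) {
    resp <- matrix(rnorm(12 * 44), 12, 44)
    cs <- channelwise_stats(resp, "greater")
    hits <- hits + sum(cs$p < 0.05)
    total <- total + nrow(cs)
  }
  expect_lt(abs(hits / total - 0.05), 0.01)

  # channels with a real effect rank top by t
  resp <- matrix(rnorm(12 * 44), 12, 44)
  resp[, 9:11] <- resp[, 9:11] + 1.5
  cs <- channelwise_stats(resp, "greater")
  expect_setequal(cs$channel[order(cs$t, decreasing = TRUE)][1:3], 9:11)

  expect_error(channelwise_stats(matrix(0, 12, 4)), "zero standard deviation")
})

test_that("HbR direction: decreases are tested with the lower tail", {
  set.seed(13)
  resp <- matrix(rnorm(12 * 4, mean = -1), 12, 4)
  rs <- roi_stats(resp, list(r1 = 1:2, r2 = 3:4), alternative = "less")
  expect_true(all(rs$t < 0))
  expect_true(all(rs$p < 0.05))
  # the same data tested for an increase is non-significant
  rs2 <- roi_stats(resp, list(r1 = 1:2, r2 = 3:4), alternative = "greater")
  expect_true(all(rs2$p > 0.5))
})
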