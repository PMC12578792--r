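#' Read a channel-to-ROI map
#'
#' @param path YAML file mapping ROI names to channel index vectors; defaults
#'   to the packaged six-ROI map (bilateral MFG, STS, TPJ).
#' @return Named list of integer channel vectors.
#' @export
read_roi_map <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "roi_map.yaml", package = "natfnirs",
                        mustWork = TRUE)
  m <- yaml::read_yaml(path)
  m <- lapply(m, as.integer)
  all_ch <- unlist(m)
  assert_that(!anyDuplicated(all_ch), "ROI channel lists must be disjoint")
  assert_that(all(lengths(m) > 0), "empty ROI in map")
  m
}

#' Aggregate channel responses into per-participant ROI values
#'
#' A participant's ROI value is the mean of their available channel
#' responses inside the ROI; participants with no surviving channel in an
#' ROI are omitted from that ROI only (which is how per-ROI degrees of
#' freedom become heterogeneous).
#'
#' @param resp Participants x channels response matrix (`NA` = missing), as
#'   from [response_matrix()].
#' @param roi_map Named list of channel vectors (see [read_roi_map()]).
#' @return Participants x ROI matrix with `NA` for omitted participants.
#' @export
roi_aggregate <- function(resp, roi_map) {
  assert_that(length(roi_map) > 0, "empty ROI map")
  assert_that(max(unlist(roi_map)) <= ncol(resp),
              "ROI map references channel beyond the response matrix")
  out <- vapply(roi_map, function(ch) {
    v <- rowMeans(resp[, ch, drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  }, numeric(nrow(resp)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(rownames(resp), names(roi_map)))
  out
}

#' One-sample t-test (closed form)
#'
#' `t = mean / (sd / sqrt(n))` against zero with `df = n - 1`; one-tailed by
#' default, matching the directional HbO (increase) / HbR (decrease)
#' hypotheses.
#'
#' @param values Numeric vector (`NA` dropped).
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return List with `t`, `df`, `p`, `n`, `mean`, `sd`.
#' @export
one_sample_t <- function(values, alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  values <- values[!is.na(values)]
  n <- length(values)
  assert_that(n >= 2, "one_sample_t needs at least two observations")
  s <- stats::sd(values)
  if (s == 0) stopf("zero standard deviation: t statistic undefined")
  t <- mean(values) / (s / sqrt(n))
  df <- n - 1
  p <- switch(alternative,
              greater = stats::pt(t, df, lower.tail = FALSE),
              less = stats::pt(t, df),
              two.sided = 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  list(t = t, df = df, p = p, n = n, mean = mean(values), sd = s)
}

#' Cohen's d for a one-sample design
#'
#' `d = mean / sd`; equals `t / sqrt(n)`.
#'
#' @param values Numeric vector (`NA` dropped).
#' @export
cohens_d <- function(values) {
  values <- values[!is.na(values)]
  assert_that(length(values) >= 2, "cohens_d needs at least two observations")
  s <- stats::sd(values)
  if (s == 0) stopf("zero standard deviation: effect size undefined")
  mean(values) / s
}

#' Post hoc power of a one-sample t-test
#'
#' Analytic power via the noncentral t distribution with noncentrality
#' `d * sqrt(n)` at significance level `alpha`.
#'
#' @param d Cohen's d.
#' @param n Sample size.
#' @param alpha Significance level.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return Power in `[0, 1]`; equals `alpha` when `d = 0` (one-sided).
#' @export
posthoc_power <- function(d, n, alpha = 0.05,
                          alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  assert_that(n >= 2, "n must be at least 2")
  df <- n - 1
  ncp <- d * sqrt(n)
  switch(alternative,
         greater = stats::pt(stats::qt(1 - alpha, df), df, ncp = ncp,
                             lower.tail = FALSE),
         less = stats::pt(stats::qt(alpha, df), df, ncp = ncp),
         two.sided = stats::pt(stats::qt(1 - alpha / 2, df), df, ncp = ncp,
                               lower.tail = FALSE) +
           stats::pt(stats::qt(alpha / 2, df), df, ncp = ncp))
}

#' False-discovery-rate adjustment
#'
#' Default Benjamini-Hochberg step-up q-values. The `"storey"` mode scales
#' BH by a user-supplied fixed null proportion `pi0` (no smoother: with a
#' handful of tests the pi0 estimators are unstable).
#'
#' @param p Vector of p-values.
#' @param method `"BH"` or `"storey"`.
#' @param pi0 Fixed null proportion for the Storey mode.
#' @return Vector of q-values, same length/order as `p`.
#' @export
fdr_adjust <- function(p, method = c("BH", "storey"), pi0 = 1) {
  method <- match.arg(method)
  if (!length(p)) return(numeric(0))
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  assert_that(pi0 > 0 && pi0 <= 1, "pi0 must lie in (0, 1]")
  q <- stats::p.adjust(p, method = "BH")
  if (method == "storey") q <- pmin(1, pi0 * q)
  q
}

stat_row <- function(values, alternative, alpha = 0.05) {
  r <- one_sample_t(values, alternative)
  d <- r$mean / r$sd
  data.frame(n = r$n, mean = r$mean, sd = r$sd, t = r$t, df = r$df, p = r$p,
             d = d, power = posthoc_power(d, r$n, alpha, alternative))
}

#' ROI-level one-tailed inference
#'
#' Aggregates responses into ROIs, runs a one-tailed one-sample t-test per
#' ROI (HbO tested for an increase, HbR for a decrease), and FDR-adjusts the
#' p-values across ROIs.
#'
#' @param resp Participants x channels response matrix.
#' @param roi_map Named list of channel vectors.
#' @param alternative Test direction (default `"greater"`, the HbO tail).
#' @param fdr_method Passed to [fdr_adjust()].
#' @return A `data.frame` with one row per ROI: `roi`, `n`, `mean`, `sd`,
#'   `t`, `df`, `p`, `q`, `d`, `power`.
#' @export
roi_stats <- function(resp, roi_map, alternative = c("greater", "less"),
                      fdr_method = "BH") {
  alternative <- match.arg(alternative)
  agg <- roi_aggregate(resp, roi_map)
  rows <- lapply(colnames(agg), function(r) {
    cbind(roi = r, stat_row(agg[, r], alternative))
  })
  out <- do.call(rbind, rows)
  out$q <- fdr_adjust(out$p, fdr_method)
  out[, c("roi", "n", "mean", "sd", "t", "df", "p", "q", "d", "power")]
}

#' Channel-wise one-tailed inference with FDR across channels
#'
#' @param resp Participants x channels response matrix.
#' @param alternative Test direction.
#' @param fdr_method Passed to [fdr_adjust()].
#' @param min_n Channels with fewer participants than this are skipped.
#' @return A `data.frame` with one row per testable channel.
#' @export
channelwise_stats <- function(resp, alternative = c("greater", "less"),
                              fdr_method = "BH", min_n = 2) {
  alternative <- match.arg(alternative)
  rows <- lapply(seq_len(ncol(resp)), function(ch) {
    v <- resp[, ch]
    v <- v[!is.na(v)]
    if (length(v) < min_n) return(NULL)
    cbind(channel = ch, stat_row(v, alternative))
  })
  out <- do.call(rbind, rows)
  assert_that(!is.null(out), "no channel has enough observations")
  out$q <- fdr_adjust(out$p, fdr_method)
  rownames(out) <- NULL
  out[, c("channel", "n", "mean", "sd", "t", "df", "p", "q", "d", "power")]
}
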