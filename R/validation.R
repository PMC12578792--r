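#' Run one onset-definition condition of the validation harness
#'
#' Executes the epoching -> statistics -> cluster pipeline on already
#' preprocessed data under a given onset shift (`0`, `3`, `6`, or
#' `"random"`), so alternative time-window definitions can be compared on
#' identical input.
#'
#' @param hb_list Named list of `hb_series`, one per participant.
#' @param events Extracted (unshifted) event `data.frame`.
#' @param shift Numeric shift in seconds or `"random"`.
#' @param params [epoch_params()] template; its `shift_s` is overridden.
#' @param roi_map Named list of ROI channel vectors.
#' @param adjacency Channel adjacency matrix.
#' @param n_perm Permutations for the cluster test.
#' @param seed Seed (random shifts and permutations).
#' @param chromophore `"hbo"` or `"hbr"` for the response tables.
#' @param exhaustive Passed to the cluster test (default auto).
#' @return A `condition_report`: per-ROI and per-channel stats, cluster
#'   test, per-channel grand-average peak latency, event count.
#' @export
run_condition <- function(hb_list, events, shift, params = epoch_params(),
                          roi_map = read_roi_map(), adjacency = read_adjacency(),
                          n_perm = 500, seed = 1L, chromophore = "hbo",
                          exhaustive = NULL) {
  params$shift_s <- if (identical(shift, "random")) "random" else as.numeric(shift)
  ev <- apply_shift(events, params, seed = seed)
  ev <- exclude_short_isi(ev, params)
  blocks <- lapply(hb_list, extract_blocks, events = ev, params = params)
  blocks <- Filter(function(b) dim(b$hbo)[1] > 0, blocks)
  assert_that(length(blocks) >= 2, "condition '%s': fewer than two participants with blocks",
              as.character(shift))
  responses <- peak_window_mean(blocks, params, chromophore)
  n_ch <- nrow(hb_list[[1]]$hbo)
  resp <- response_matrix(responses, n_ch)
  alt <- if (chromophore == "hbo") "greater" else "less"
  roi <- roi_stats(resp, roi_map, alternative = alt)
  chan <- channelwise_stats(resp, alternative = alt)
  clus <- cluster_permutation_test(blocks, adjacency, params,
                                   n_perm = n_perm, seed = seed,
                                   exhaustive = exhaustive)
  grand <- grand_average(blocks)
  lat <- peak_latency(grand, params, chromophore)
  structure(list(
    condition = as.character(shift),
    n_events = nrow(ev),
    params = params,
    roi = roi,
    channels = chan,
    cluster = clus,
    latency_s = lat,
    grand_average = grand
  ), class = "condition_report")
}

#' Compare validation conditions
#'
#' Descriptive comparison (the protocol's validation is by inspection, not
#' formal testing): per-condition summary of ROI significance, cluster mass
#' and p, and per-channel peak-latency deltas relative to the first report.
#'
#' @param reports List of `condition_report`s (first one is the reference).
#' @return A `validation_report`: `summary` data frame, `latency_delta_s`
#'   and `roi_t_delta` matrices (condition x channel / x ROI, relative to
#'   the reference condition).
#' @export
compare_conditions <- function(reports) {
  assert_that(length(reports) >= 1, "need at least one condition report")
  n_ch <- length(reports[[1]]$latency_s)
  for (r in reports) {
    assert_that(length(r$latency_s) == n_ch,
                "condition reports have mismatched channel sets")
  }
  ref <- reports[[1]]
  summ <- do.call(rbind, lapply(reports, function(r) {
    top_mass <- if (length(r$cluster$clusters)) r$cluster$clusters[[1]]$mass else 0
    top_p <- if (length(r$cluster$clusters)) r$cluster$clusters[[1]]$p else NA_real_
    data.frame(condition = r$condition,
               n_events = r$n_events,
               max_roi_t = max(r$roi$t),
               min_roi_p = min(r$roi$p),
               n_roi_sig_p05 = sum(r$roi$p < 0.05),
               n_roi_sig_q05 = sum(r$roi$q < 0.05),
               cluster_mass = top_mass,
               cluster_p = top_p,
               cluster_sig = !is.na(top_p) && top_p < 0.05,
               stringsAsFactors = FALSE)
  }))
  lat <- do.call(rbind, lapply(reports, function(r) r$latency_s - ref$latency_s))
  rownames(lat) <- vapply(reports, `[[`, character(1), "condition")
  roi_t <- do.call(rbind, lapply(reports, function(r) {
    stats::setNames(r$roi$t, r$roi$roi) - stats::setNames(ref$roi$t, ref$roi$roi)
  }))
  rownames(roi_t) <- rownames(lat)
  structure(list(summary = summ, latency_delta_s = lat, roi_t_delta = roi_t,
                 reference = ref$condition),
            class = "validation_report")
}

#' Run the full onset-shift validation harness
#'
#' @param hb_list Named list of `hb_series`.
#' @param events Extracted event `data.frame`.
#' @param conditions Vector of shifts (numbers and/or `"random"`); the first
#'   is the reference.
#' @param ... Passed to [run_condition()].
#' @return A `validation_report` with the per-condition reports attached as
#'   attribute `reports`.
#' @export
run_validation <- function(hb_list, events, conditions = c(3, 0, 6, "random"),
                           ...) {
  reports <- lapply(conditions, function(s)
    run_condition(hb_list, events, shift = s, ...))
  out <- compare_conditions(reports)
  attr(out, "reports") <- reports
  out
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> reference condition: +%s s shift\n", x$reference))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
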