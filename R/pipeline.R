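#' Run the full analysis pipeline end to end
#'
#' Orchestrates simulate (optional) -> event extraction -> preprocessing ->
#' epoching -> ROI/channel statistics -> cluster permutation -> onset-shift
#' validation, writing tidy CSV outputs and a provenance manifest. With a
#' `sim_config` the study is simulated; annotation files are written and
#' read back through the package's own reader so the text formats are
#' exercised on every run.
#'
#' @param cfg A [sim_config()] describing the study to simulate.
#' @param out_dir Output directory (created if needed); `NULL` for none.
#' @param criteria [event_criteria()].
#' @param pparams [preproc_params()].
#' @param eparams [epoch_params()].
#' @param roi_map,adjacency Analysis configuration (defaults packaged).
#' @param conditions Validation conditions; the first is the main analysis.
#' @param n_perm Cluster-test permutations.
#' @param write_recordings Also write the raw recordings as CSV (large).
#' @return List with the event tables, gate report, responses, ROI/channel
#'   stats, cluster test, validation report, and the manifest.
#' @export
run_pipeline <- function(cfg = sim_config(), out_dir = NULL,
                         criteria = event_criteria(),
                         pparams = preproc_params(),
                         eparams = epoch_params(),
                         roi_map = read_roi_map(),
                         adjacency = read_adjacency(),
                         conditions = c(3, 0, 6, "random"),
                         n_perm = 1000,
                         write_recordings = FALSE) {
  assert_that(nrow(adjacency) == cfg$n_channels,
              "adjacency has %d channels but the recordings have %d",
              nrow(adjacency), cfg$n_channels)
  assert_that(max(unlist(roi_map)) <= cfg$n_channels,
              "ROI map references channel beyond the recording")
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  study <- simulate_study(cfg)
  ann_path <- if (!is.null(out_dir)) file.path(out_dir, "annotations.tsv") else
    tempfile(fileext = ".tsv")
  write_annotations(study$bouts, ann_path)
  bouts <- read_annotations(ann_path)

  merged <- merge_bouts(bouts, criteria$gap_merge_ms)
  events <- extract_events(merged, criteria)
  gate <- participant_gate(events, criteria,
                           participants = names(study$recordings))
  events <- events[events$participant %in% gate$kept, , drop = FALSE]

  hb_list <- list()
  excluded <- character(0)
  for (id in gate$kept) {
    hb <- tryCatch(preprocess(study$recordings[[id]], pparams),
                   natfnirs_recording_rejected = function(e) {
                     message(sprintf("pipeline: %s", conditionMessage(e)))
                     NULL
                   })
    if (is.null(hb)) excluded <- c(excluded, id) else hb_list[[id]] <- hb
  }
  assert_that(length(hb_list) >= 2, "fewer than two usable participants")
  events <- events[events$participant %in% names(hb_list), , drop = FALSE]

  validation <- run_validation(hb_list, events, conditions = conditions,
                               params = eparams, roi_map = roi_map,
                               adjacency = adjacency, n_perm = n_perm,
                               seed = cfg$seed)
  main <- attr(validation, "reports")[[1]]

  manifest <- list(
    package_version = as.character(utils::packageVersion("natfnirs")),
    seed = cfg$seed,
    n_participants = cfg$n_participants,
    participants_excluded_preproc = excluded,
    gate = gate$report,
    event_criteria = unclass(criteria),
    preproc_params = unclass(pparams),
    epoch_params = unclass(main$params),
    conditions = as.character(conditions),
    n_perm = n_perm,
    annotations_md5 = unname(tools::md5sum(ann_path))
  )

  if (!is.null(out_dir)) {
    utils::write.csv(main$roi, file.path(out_dir, "roi_stats.csv"), row.names = FALSE)
    utils::write.csv(main$channels, file.path(out_dir, "channel_stats.csv"), row.names = FALSE)
    utils::write.csv(validation$summary, file.path(out_dir, "validation_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(gate$report, file.path(out_dir, "participant_gate.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(clusters = lapply(main$cluster$clusters, function(cl)
        list(channels = cl$channels, mass = cl$mass, p = cl$p)),
        null_max_mass = main$cluster$null_max_mass),
      file.path(out_dir, "cluster_result.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    if (write_recordings) {
      for (id in names(study$recordings)) {
        write_recording_csv(study$recordings[[id]],
                            file.path(out_dir, sprintf("recording_%s.csv", id)))
        write_ground_truth(study$truths[[id]],
                           file.path(out_dir, sprintf("truth_%s.json", id)))
      }
    }
  }

  list(bouts = bouts, events = events, gate = gate$report,
       hb_list = hb_list, main = main, validation = validation,
       manifest = manifest)
}
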