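#' Sustained-attention event criteria
#'
#' Rules that turn coded look bouts into sustained-attention events: gaps of
#' at most `gap_merge_ms` do not terminate an observation, only looks
#' strictly longer than `min_look_s` qualify, analysed duration is capped at
#' `max_block_s`, and participants must contribute at least
#' `min_events_per_participant` events.
#'
#' @param min_look_s Minimum look duration in seconds (strict inequality).
#' @param max_block_s Cap on analysed event duration in seconds.
#' @param gap_merge_ms Look-aways up to this many milliseconds are bridged.
#' @param min_events_per_participant Participant inclusion threshold.
#' @param allowed_targets Targets eligible as events (default `"toy"`).
#' @export
event_criteria <- function(min_look_s = 8, max_block_s = 15, gap_merge_ms = 100,
                           min_events_per_participant = 5,
                           allowed_targets = "toy") {
  assert_that(min_look_s < max_block_s, "min_look_s must be below max_block_s")
  assert_that(gap_merge_ms >= 0, "gap_merge_ms must be >= 0")
  assert_that(is_count(min_events_per_participant),
              "min_events_per_participant must be a count")
  structure(as.list(environment()), class = "event_criteria")
}

#' Read a tab-delimited look-bout annotation export
#'
#' Expects a header line `participant	target	start_s	end_s` followed by one
#' bout per line (ELAN-export style, reconciled single-coder file). Rows are
#' validated and returned sorted by participant and onset.
#'
#' @param path Path to the annotation file.
#' @return A look-bout `data.frame` (`participant`, `target`, `start_s`,
#'   `end_s`).
#' @export
read_annotations <- function(path) {
  assert_that(file.exists(path), "annotation file not found: %s", path)
  lines <- readLines(path)
  assert_that(length(lines) >= 1, "annotation file %s is empty (no header)", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  assert_that(identical(header, c("participant", "target", "start_s", "end_s")),
              "annotation header must be 'participant\ttarget\tstart_s\tend_s' in %s", path)
  body <- lines[-1]
  body_idx <- which(nzchar(trimws(body)))
  rows <- lapply(body_idx, function(i) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 4)
      stopf("malformed annotation row at line %d of %s (expected 4 fields, got %d)",
            i + 1L, path, length(f), class = "natfnirs_parse_error")
    st <- suppressWarnings(as.numeric(f[3])); en <- suppressWarnings(as.numeric(f[4]))
    if (is.na(st) || is.na(en))
      stopf("non-numeric time at line %d of %s", i + 1L, path,
            class = "natfnirs_parse_error")
    if (en <= st)
      stopf("end_s <= start_s at line %d of %s", i + 1L, path,
            class = "natfnirs_parse_error")
    data.frame(participant = f[1], target = f[2], start_s = st, end_s = en,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(participant = character(0), target = character(0),
               start_s = numeric(0), end_s = numeric(0))
  out[order(out$participant, out$start_s), , drop = FALSE]
}

#' Write look bouts to the tab-delimited annotation format
#'
#' @param bouts Look-bout `data.frame`.
#' @param path Output path.
#' @export
write_annotations <- function(bouts, path) {
  utils::write.table(bouts[, c("participant", "target", "start_s", "end_s")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge look bouts across brief look-aways
#'
#' Consecutive same-target bouts of one participant separated by a gap of at
#' most `gap_merge_ms` are fused into one observation spanning the first
#' start to the last end (the "look-aways of more than 100 ms end an
#' observation" rule). Idempotent.
#'
#' @param bouts Look-bout `data.frame`, sorted within participant.
#' @param gap_merge_ms Maximum bridged gap in milliseconds.
#' @return Merged look-bout `data.frame`.
#' @export
merge_bouts <- function(bouts, gap_merge_ms = 100) {
  if (!nrow(bouts)) return(bouts)
  gap_s <- gap_merge_ms / 1000
  out <- lapply(split(bouts, bouts$participant), function(b) {
    b <- b[order(b$start_s), , drop = FALSE]
    keep <- b[1, , drop = FALSE]
    for (i in seq_len(nrow(b))[-1]) {
      j <- nrow(keep)
      if (b$target[i] == keep$target[j] &&
          b$start_s[i] - keep$end_s[j] <= gap_s + 1e-12) {
        keep$end_s[j] <- max(keep$end_s[j], b$end_s[i])
      } else {
        keep <- rbind(keep, b[i, , drop = FALSE])
      }
    }
    keep
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[order(out$participant, out$start_s), , drop = FALSE]
}

#' Extract sustained-attention events from merged look bouts
#'
#' One event per merged bout whose duration strictly exceeds
#' `criteria$min_look_s` and whose target is allowed; the analysed duration
#' is capped at `criteria$max_block_s`.
#'
#' @param bouts Merged look-bout `data.frame`.
#' @param criteria An [event_criteria()].
#' @return An event `data.frame` with columns `participant`, `target`,
#'   `look_onset_s`, `duration_s` (capped), `shift_s` (0 until
#'   [apply_shift()]), `onset_s` (shifted onset, equals `look_onset_s` here).
#' @export
extract_events <- function(bouts, criteria = event_criteria()) {
  stopifnot(inherits(criteria, "event_criteria"))
  dur <- bouts$end_s - bouts$start_s
  sel <- dur > criteria$min_look_s & bouts$target %in% criteria$allowed_targets
  ev <- data.frame(
    participant = bouts$participant[sel],
    target = bouts$target[sel],
    look_onset_s = bouts$start_s[sel],
    duration_s = pmin(dur[sel], criteria$max_block_s),
    shift_s = rep(0, sum(sel)),
    stringsAsFactors = FALSE
  )
  ev$onset_s <- ev$look_onset_s
  ev <- ev[order(ev$participant, ev$look_onset_s), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Gate participants on a minimum event count
#'
#' @param events Event `data.frame` from [extract_events()].
#' @param criteria An [event_criteria()].
#' @param participants Optional full participant roster (so participants with
#'   zero events appear in the report).
#' @return List with `kept` (character vector of retained participants) and
#'   `report` (`data.frame` of per-participant event counts and inclusion).
#' @export
participant_gate <- function(events, criteria = event_criteria(),
                             participants = NULL) {
  stopifnot(inherits(criteria, "event_criteria"))
  ids <- union(participants, unique(events$participant))
  counts <- vapply(ids, function(p) sum(events$participant == p), integer(1))
  report <- data.frame(participant = ids, n_events = counts,
                       included = counts >= criteria$min_events_per_participant,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(kept = report$participant[report$included], report = report)
}
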