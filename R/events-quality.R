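#' Subject-level recording-quality filter
#'
#' Excludes subjects who spend more than `max_bad_fraction` of their total
#' recording time blinking or fixating outside the video frame boundary,
#' pooled over all of the subject's streams. This mirrors the standard
#' pupillometry exclusion of participants whose signal is dominated by blink
#' loss or off-screen gaze.
#'
#' @param events An events tibble covering one or more subjects.
#' @param aoi An AOI tibble (provides the frame rectangle per video and
#'   modality); alternatively `frame_rect` may be given directly.
#' @param max_bad_fraction Exclusion threshold on the bad-time fraction
#'   (default 0.06, i.e. > 6 percent is excluded).
#' @param frame_rect Optional numeric `c(x0, y0, x1, y1)` used for every
#'   stream instead of per-stream lookup in `aoi`.
#' @param stream_duration_ms Optional tibble (`subject_id`, `video_id`,
#'   `duration_ms`) giving true recording lengths. When absent, the latest
#'   event end per stream is used.
#' @return A list with `kept` (events of retained subjects), `summary` (one
#'   row per subject: blink time, out-of-frame fixation time, total time,
#'   `bad_fraction`, `excluded`, `reason`), and `excluded_subjects`.
#' @export
quality_filter <- function(events, aoi = NULL, max_bad_fraction = 0.06,
                           frame_rect = NULL, stream_duration_ms = NULL) {
  validate_events(events)
  if (nrow(events) == 0) stop_pf("quality_filter needs a non-empty events table")
  if (is.null(aoi) && is.null(frame_rect)) {
    stop_pf("either an AOI table or a frame_rect must be supplied")
  }
  streams <- events |>
    dplyr::group_by(.data$subject_id, .data$video_id, .data$modality) |>
    dplyr::summarise(last_end = max(.data$end_ms), .groups = "drop")
  if (!is.null(stream_duration_ms)) {
    streams <- dplyr::left_join(
      streams, stream_duration_ms,
      by = intersect(c("subject_id", "video_id"), names(stream_duration_ms))
    )
    streams$total_ms <- dplyr::coalesce(streams$duration_ms, streams$last_end)
  } else {
    streams$total_ms <- streams$last_end
  }
  if (any(streams$total_ms <= 0)) stop_pf("zero-duration recording encountered")

  per_stream <- purrr::pmap_dfr(
    streams[, c("subject_id", "video_id", "modality", "total_ms")],
    function(subject_id, video_id, modality, total_ms) {
      ev <- events[events$subject_id == subject_id & events$video_id == video_id, ,
                   drop = FALSE]
      fr <- if (!is.null(frame_rect)) frame_rect else
        frame_rect_for(aoi, video_id, modality)
      fix <- ev[ev$event_type == "FIX", , drop = FALSE]
      out_frame <- fix$x_px < fr[1] | fix$x_px >= fr[3] |
        fix$y_px < fr[2] | fix$y_px >= fr[4]
      tibble::tibble(
        subject_id = subject_id,
        blink_ms = sum(ev$duration_ms[ev$event_type == "BLINK"]),
        offframe_ms = sum(fix$duration_ms[out_frame]),
        total_ms = total_ms
      )
    }
  )
  summary <- per_stream |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      blink_ms = sum(.data$blink_ms),
      offframe_ms = sum(.data$offframe_ms),
      total_ms = sum(.data$total_ms),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      bad_fraction = (.data$blink_ms + .data$offframe_ms) / .data$total_ms,
      excluded = .data$bad_fraction > max_bad_fraction,
      reason = ifelse(.data$excluded,
                      sprintf("bad-time fraction %.3f > %.3f",
                              .data$bad_fraction, max_bad_fraction),
                      "")
    )
  kept_ids <- summary$subject_id[!summary$excluded]
  kept <- events[events$subject_id %in% kept_ids, , drop = FALSE]
  class(kept) <- class(events)
  list(
    kept = kept,
    summary = summary,
    excluded_subjects = summary$subject_id[summary$excluded]
  )
}
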