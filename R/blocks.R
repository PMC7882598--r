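#' Segment event streams into fixed-length prediction blocks
#'
#' Each stream is cut into consecutive, non-overlapping blocks of `block_s`
#' seconds anchored at the stream start; the trailing partial block is
#' discarded. Within a block, the first `input_s` seconds form the input
#' window and the remainder the output window. An event belongs to a window
#' iff its onset (`start_ms`) lies in the window. The block label is the
#' unweighted mean pupil diameter over output-window fixations; blocks
#' lacking a fixation in either window are dropped (their count is attached
#' as attribute `n_dropped`).
#'
#' @param events An events tibble (one or more streams).
#' @param block_s Block length in seconds (15 or 20 in the reference
#'   protocol).
#' @param input_s Input-window length in seconds (default 10).
#' @param duration_ms Optional recording length in ms: a single number
#'   applied to every stream, or a tibble (`subject_id`, `video_id`,
#'   `duration_ms`). Defaults to the latest event end per stream.
#' @return A tibble (class `pupil_blocks`), one row per retained block, with
#'   identifiers, window bounds (ms), `label_um`, `input_mean_um`, event
#'   counts, and list-columns `input_fix`, `input_sacc`, `input_blink`
#'   holding the input-window events of each channel.
#' @export
segment_blocks <- function(events, block_s = 15, input_s = 10,
                           duration_ms = NULL) {
  if (!(block_s > input_s && input_s > 0)) {
    stop_pf("block_s must exceed input_s and input_s must be positive")
  }
  validate_events(events)
  if (nrow(events) == 0) return(empty_blocks())
  streams <- events |>
    dplyr::group_by(.data$subject_id, .data$video_id, .data$modality) |>
    dplyr::summarise(last_end = max(.data$end_ms), .groups = "drop")
  if (is.numeric(duration_ms) && length(duration_ms) == 1) {
    streams$dur <- duration_ms
  } else if (is.data.frame(duration_ms)) {
    streams <- dplyr::left_join(streams, duration_ms,
                                by = intersect(c("subject_id", "video_id"),
                                               names(duration_ms)))
    streams$dur <- dplyr::coalesce(streams$duration_ms, streams$last_end)
  } else {
    streams$dur <- streams$last_end
  }
  block_ms <- block_s * 1000
  input_ms <- input_s * 1000
  n_dropped <- 0L
  out <- purrr::pmap_dfr(
    streams[, c("subject_id", "video_id", "modality", "dur")],
    function(subject_id, video_id, modality, dur) {
      ev <- events[events$subject_id == subject_id &
                     events$video_id == video_id, , drop = FALSE]
      n_cand <- floor(dur / block_ms)
      if (n_cand < 1) return(NULL)
      purrr::map_dfr(seq_len(n_cand), function(b) {
        t0 <- (b - 1) * block_ms
        t_in_end <- t0 + input_ms
        t_end <- t0 + block_ms
        win <- ev[ev$start_ms >= t0 & ev$start_ms < t_end, , drop = FALSE]
        in_win <- win[win$start_ms < t_in_end, , drop = FALSE]
        out_win <- win[win$start_ms >= t_in_end, , drop = FALSE]
        in_fix <- in_win[in_win$event_type == "FIX", , drop = FALSE]
        out_fix <- out_win[out_win$event_type == "FIX", , drop = FALSE]
        if (nrow(in_fix) == 0 || nrow(out_fix) == 0) {
          n_dropped <<- n_dropped + 1L
          return(NULL)
        }
        tibble::tibble(
          subject_id = subject_id, video_id = video_id, modality = modality,
          block_id = as.integer(b), t0_ms = t0, input_end_ms = t_in_end,
          end_ms = t_end,
          label_um = mean(out_fix$pupil_um),
          input_mean_um = mean(in_fix$pupil_um),
          n_input_fix = nrow(in_fix), n_output_fix = nrow(out_fix),
          input_fix = list(in_fix),
          input_sacc = list(in_win[in_win$event_type == "SACC", , drop = FALSE]),
          input_blink = list(in_win[in_win$event_type == "BLINK", , drop = FALSE])
        )
      })
    }
  )
  if (nrow(out) == 0) out <- empty_blocks()
  class(out) <- unique(c("pupil_blocks", class(out)))
  attr(out, "block_s") <- block_s
  attr(out, "input_s") <- input_s
  attr(out, "n_dropped") <- n_dropped
  out
}

empty_blocks <- function() {
  out <- tibble::tibble(
    subject_id = character(), video_id = character(), modality = character(),
    block_id = integer(), t0_ms = numeric(), input_end_ms = numeric(),
    end_ms = numeric(), label_um = numeric(), input_mean_um = numeric(),
    n_input_fix = integer(), n_output_fix = integer(),
    input_fix = list(), input_sacc = list(), input_blink = list()
  )
  class(out) <- c("pupil_blocks", class(out))
  out
}

#' Output-window label of a block
#'
#' The label is the unweighted arithmetic mean of the pupil diameters of the
#' output-window fixations.
#'
#' @param output_fix A tibble of output-window fixations with a `pupil_um`
#'   column.
#' @return The label in micrometres.
#' @export
label_block <- function(output_fix) {
  if (nrow(output_fix) == 0) stop_pf("a block needs at least one output-window fixation")
  mean(output_fix$pupil_um)
}

#' Map fixation positions to AOI codes
#'
#' A fixation is assigned to the first region (in priority order) whose
#' half-open rectangle `[x0, x1) x [y0, y1)` contains its position, and to
#' `NONE` when no region contains it. The half-open convention means a point
#' on a shared edge belongs to at most one rectangle; if it lies inside the
#' closures of several, the priority order decides.
#'
#' @param x,y Fixation positions in pixels (vectors of equal length).
#' @param aoi_one AOI tibble rows for a single (video, modality).
#' @return A character vector of AOI names (`"NONE"` where unassigned).
#' @export
map_fixation_to_aoi <- function(x, y, aoi_one) {
  if (length(x) != length(y)) stop_pf("x and y must have equal length")
  if (nrow(aoi_one) == 0) return(rep("NONE", length(x)))
  aoi_one <- aoi_one[order(aoi_one$priority), , drop = FALSE]
  out <- rep("NONE", length(x))
  for (i in rev(seq_len(nrow(aoi_one)))) {
    hit <- x >= aoi_one$x0[i] & x < aoi_one$x1[i] &
      y >= aoi_one$y0[i] & y < aoi_one$y1[i]
    out[hit] <- aoi_one$name[i]
  }
  out
}

#' Export a block table for audit or tabular modeling
#'
#' Writes the scalar columns of a block table (identifiers, window bounds,
#' label, input mean, counts) to a delimited file.
#'
#' @param blocks A `pupil_blocks` tibble.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_block_table <- function(blocks, path) {
  scalar <- blocks[, !vapply(blocks, is.list, logical(1)), drop = FALSE]
  readr::write_tsv(scalar, path, progress = FALSE)
  invisible(path)
}
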