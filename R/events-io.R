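#' Read an eye-tracking event report
#'
#' Parses a delimited event report (tab- or comma-separated) with one row per
#' classified eye event. The canonical columns are `subject_id`, `video_id`,
#' `modality`, `event_type` (one of `FIX`, `SACC`, `BLINK`), `start_ms`,
#' `end_ms`, `x_px`, `y_px`, `end_x_px`, `end_y_px` and `pupil_um`; columns
#' that do not apply to an event type are left blank. Exports from vendor
#' software with different column names can be mapped through `dialect`.
#'
#' Rows that cannot be interpreted (non-numeric times, `end_ms <= start_ms`,
#' fixations without a positive pupil diameter or position, unknown event
#' type) are dropped, counted and reported via a warning; the count is
#' attached as the `n_malformed` attribute. Events are returned sorted by
#' subject, video and onset.
#'
#' @param path Path to the delimited report.
#' @param dialect Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(subject_id = "RECORDING_SESSION_LABEL")`.
#' @return A tibble of events (class `pupil_events`), one stream per
#'   (subject, video) pair, with a derived `duration_ms` column.
#' @seealso [write_event_report()], [validate_events()]
#' @export
read_event_report <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_pf("event report not found: %s", path)
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (!is.null(dialect)) {
    for (canon in names(dialect)) {
      if (dialect[[canon]] %in% names(raw)) {
        names(raw)[names(raw) == dialect[[canon]]] <- canon
      }
    }
  }
  assert_cols(raw, setdiff(.EVENT_COLS, c("end_x_px", "end_y_px")), "event report")
  if (!"end_x_px" %in% names(raw)) raw$end_x_px <- NA_character_
  if (!"end_y_px" %in% names(raw)) raw$end_y_px <- NA_character_
  if (nrow(raw) == 0) {
    ev <- empty_events()
    attr(ev, "n_malformed") <- 0L
    return(ev)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  ev <- tibble::tibble(
    subject_id = as.character(raw$subject_id),
    video_id = as.character(raw$video_id),
    modality = as.character(raw$modality),
    event_type = toupper(as.character(raw$event_type)),
    start_ms = num(raw$start_ms),
    end_ms = num(raw$end_ms),
    x_px = num(raw$x_px),
    y_px = num(raw$y_px),
    end_x_px = num(raw$end_x_px),
    end_y_px = num(raw$end_y_px),
    pupil_um = num(raw$pupil_um)
  )
  ok <- !is.na(ev$start_ms) & !is.na(ev$end_ms) & ev$end_ms > ev$start_ms &
    ev$event_type %in% c("FIX", "SACC", "BLINK") &
    !is.na(ev$subject_id) & !is.na(ev$video_id)
  is_fix <- ev$event_type == "FIX"
  ok[is_fix] <- ok[is_fix] & !is.na(ev$pupil_um[is_fix]) & ev$pupil_um[is_fix] > 0 &
    !is.na(ev$x_px[is_fix]) & !is.na(ev$y_px[is_fix])
  n_bad <- sum(!ok)
  if (n_bad > 0) warn_pf("dropped %d malformed event row(s)", n_bad)
  ev <- ev[ok, , drop = FALSE]
  ev <- dplyr::arrange(ev, .data$subject_id, .data$video_id, .data$start_ms)
  ev$duration_ms <- ev$end_ms - ev$start_ms
  class(ev) <- c("pupil_events", class(ev))
  attr(ev, "n_malformed") <- n_bad
  validate_events(ev)
  ev
}

empty_events <- function() {
  ev <- tibble::tibble(
    subject_id = character(), video_id = character(), modality = character(),
    event_type = character(), start_ms = numeric(), end_ms = numeric(),
    x_px = numeric(), y_px = numeric(), end_x_px = numeric(),
    end_y_px = numeric(), pupil_um = numeric(), duration_ms = numeric()
  )
  class(ev) <- c("pupil_events", class(ev))
  ev
}

#' Write an eye-tracking event report
#'
#' Serializes an events table to the canonical tab-delimited report; the file
#' round-trips through [read_event_report()] field-for-field.
#'
#' @param events An events tibble as returned by [read_event_report()] or
#'   [generate_study()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_event_report <- function(events, path) {
  validate_events(events)
  out <- events[, intersect(.EVENT_COLS, names(events)), drop = FALSE]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Validate the event-table invariants
#'
#' Checks that each (subject, video, event-type) list is sorted by onset with
#' no overlapping events, that all times are non-negative with
#' `end_ms > start_ms`, and that fixation pupil diameters are positive.
#' Errors on the first violation; returns the input invisibly otherwise.
#'
#' @param events An events tibble.
#' @export
validate_events <- function(events) {
  assert_cols(events, setdiff(.EVENT_COLS, c("end_x_px", "end_y_px")), "events table")
  if (nrow(events) == 0) return(invisible(events))
  if (any(events$end_ms <= events$start_ms)) {
    stop_pf("events with end_ms <= start_ms present")
  }
  if (any(events$start_ms < 0)) stop_pf("events with negative start_ms present")
  fix <- events[events$event_type == "FIX", , drop = FALSE]
  if (any(is.na(fix$pupil_um)) || any(fix$pupil_um <= 0)) {
    stop_pf("fixations must carry a positive pupil_um")
  }
  bad <- events |>
    dplyr::group_by(.data$subject_id, .data$video_id, .data$event_type) |>
    dplyr::summarise(
      unsorted = is.unsorted(.data$start_ms),
      overlap = {
        o <- order(.data$start_ms)
        s <- .data$start_ms[o]
        e <- .data$end_ms[o]
        length(s) > 1 && any(s[-1] < e[-length(e)])
      },
      .groups = "drop"
    )
  if (any(bad$unsorted)) stop_pf("event lists must be sorted by start_ms")
  if (any(bad$overlap)) stop_pf("overlapping events within a stream's event list")
  invisible(events)
}

#' Read an AOI definition file
#'
#' Reads a JSON file of named area-of-interest rectangles per (video,
#' modality), each entry carrying a `frame_rect` and a priority-ordered list
#' of `aois` (`INSTRUCTOR`, `TEXT`, `IMAGE` for the full modality; `TEXT` and
#' `IMAGE` for dual/single). Rectangles are half-open
#' `[x0, x1) x [y0, y1)` in pixels with the origin at the top-left.
#'
#' @param path Path to the JSON AOI file.
#' @return A tibble (class `pupil_aoi`) with one row per AOI region:
#'   `video_id`, `modality`, `name`, `x0`, `y0`, `x1`, `y1`, `priority`, and
#'   the frame rectangle `frame_x0` ... `frame_y1`.
#' @export
read_aoi_set <- function(path) {
  if (!file.exists(path)) stop_pf("AOI file not found: %s", path)
  js <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- purrr::map_dfr(js, function(entry) {
    fr <- as.numeric(unlist(entry$frame_rect))
    purrr::imap_dfr(entry$aois, function(a, i) {
      r <- as.numeric(unlist(a$rect))
      tibble::tibble(
        video_id = as.character(entry$video_id),
        modality = as.character(entry$modality),
        name = as.character(a$name),
        x0 = r[1], y0 = r[2], x1 = r[3], y1 = r[4],
        priority = as.integer(i),
        frame_x0 = fr[1], frame_y0 = fr[2], frame_x1 = fr[3], frame_y1 = fr[4]
      )
    })
  })
  class(rows) <- c("pupil_aoi", class(rows))
  validate_aoi(rows)
  rows
}

#' Write an AOI definition file
#'
#' @param aoi An AOI tibble as returned by [read_aoi_set()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_aoi_set <- function(aoi, path) {
  validate_aoi(aoi)
  entries <- aoi |>
    dplyr::group_by(.data$video_id, .data$modality) |>
    dplyr::group_map(function(g, key) {
      list(
        video_id = key$video_id,
        modality = key$modality,
        frame_rect = c(g$frame_x0[1], g$frame_y0[1], g$frame_x1[1], g$frame_y1[1]),
        aois = purrr::map(seq_len(nrow(g))[order(g$priority)], function(i) {
          list(name = g$name[i], rect = c(g$x0[i], g$y0[i], g$x1[i], g$y1[i]))
        })
      )
    })
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Validate an AOI table
#'
#' Checks AOI names, containment of regions within the frame rectangle, and
#' the per-modality region counts (3 for full, 2 for dual/single). Errors on
#' the first violation; returns the input invisibly otherwise.
#'
#' @param aoi An AOI tibble.
#' @export
validate_aoi <- function(aoi) {
  assert_cols(aoi, c("video_id", "modality", "name", "x0", "y0", "x1", "y1",
                     "priority", "frame_x0", "frame_y0", "frame_x1", "frame_y1"),
              "AOI table")
  bad_name <- setdiff(unique(aoi$name), .AOI_NAMES)
  if (length(bad_name) > 0) {
    stop_pf("unknown AOI name(s): %s", paste(bad_name, collapse = ", "))
  }
  inside <- aoi$x0 >= aoi$frame_x0 & aoi$x1 <= aoi$frame_x1 &
    aoi$y0 >= aoi$frame_y0 & aoi$y1 <= aoi$frame_y1 &
    aoi$x1 > aoi$x0 & aoi$y1 > aoi$y0
  if (!all(inside)) {
    stop_pf("AOI rectangle(s) outside the frame rectangle for: %s",
            paste(unique(aoi$name[!inside]), collapse = ", "))
  }
  counts <- aoi |>
    dplyr::group_by(.data$video_id, .data$modality) |>
    dplyr::summarise(k = dplyr::n(), full = .data$modality[1] == "full",
                     .groups = "drop")
  if (any(counts$full & counts$k != 3L)) {
    stop_pf("full-modality AOI sets must contain 3 regions")
  }
  if (any(!counts$full & counts$k != 2L)) {
    stop_pf("dual/single-modality AOI sets must contain 2 regions")
  }
  invisible(aoi)
}

# frame rectangle lookup for one (video, modality)
frame_rect_for <- function(aoi, video_id, modality) {
  g <- aoi[aoi$video_id == video_id & aoi$modality == modality, , drop = FALSE]
  if (nrow(g) == 0) stop_pf("no AOI entry for video '%s' modality '%s'", video_id, modality)
  c(g$frame_x0[1], g$frame_y0[1], g$frame_x1[1], g$frame_y1[1])
}

#' Read or write a subject score table
#'
#' The score table is a comma-delimited file with columns `subject_id` and
#' `score` (fraction correct on the post-viewing assessment, in `[0, 1]`); a
#' `modality` column is carried through when present.
#'
#' @param path File path.
#' @return A tibble with one row per subject.
#' @export
read_scores <- function(path) {
  if (!file.exists(path)) stop_pf("scores file not found: %s", path)
  sc <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(sc, c("subject_id", "score"), "scores table")
  sc$subject_id <- as.character(sc$subject_id)
  if (any(is.na(sc$score)) || any(sc$score < 0 | sc$score > 1)) {
    stop_pf("scores must lie in [0, 1]")
  }
  sc
}

#' @rdname read_scores
#' @param scores A tibble with `subject_id` and `score` columns.
#' @export
write_scores <- function(scores, path) {
  assert_cols(scores, c("subject_id", "score"), "scores table")
  readr::write_csv(scores, path, progress = FALSE)
  invisible(path)
}
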