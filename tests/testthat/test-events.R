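test_that("event reports round-trip field-for-field", {
  for (seed in 1:8) {
    ev <- dplyr::bind_rows(
      random_stream("sA", "v1", n_fix = 4, seed = seed),
      random_stream("sB", "v2", n_fix = 6, seed = seed + 100)
    )
    ev <- dplyr::arrange(ev, subject_id, video_id, start_ms)
    class(ev) <- c("pupil_events", class(ev))
    path <- withr::local_tempfile(fileext = ".tsv")
    write_event_report(ev, path)
    back <- read_event_report(path)
    cmp <- back[, names(ev)]
    attr(cmp, "n_malformed") <- NULL
    expect_equal(as.data.frame(cmp), as.data.frame(ev), tolerance = 1e-12)
  }
})

test_that("a two-fixation file yields one sorted stream", {
  ev <- make_events(fix = tibble::tibble(
    start = c(500, 100), end = c(800, 400),
    x = c(1, 2), y = c(3, 4), p = c(2000, 2100)
  ))
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(ev[order(-ev$start_ms), names(ev) != "duration_ms"], path)
  back <- read_event_report(path)
  expect_equal(nrow(back), 2)
  expect_false(is.unsorted(back$start_ms))
  expect_equal(dplyr::n_distinct(back$subject_id, back$video_id), 1)
})

test_that("an empty file with a valid header reads as an empty table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_event_report(empty_events <- make_events(), path)
  back <- read_event_report(path)
  expect_equal(nrow(back), 0)
})

test_that("dialect maps vendor column names onto the canonical schema", {
  ev <- make_regular_stream(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- ev[, names(ev) != "duration_ms"]
  names(out)[names(out) == "subject_id"] <- "RECORDING_SESSION_LABEL"
  readr::write_tsv(out, path)
  expect_error(read_event_report(path), "subject_id")
  back <- read_event_report(path, dialect = c(subject_id = "RECORDING_SESSION_LABEL"))
  expect_equal(back$subject_id, ev$subject_id)
})

test_that("malformed rows are dropped and counted", {
  ev <- make_regular_stream(3)
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- ev[, names(ev) != "duration_ms"]
  out$end_ms[2] <- out$start_ms[2] - 5   # inverted interval
  out$pupil_um[3] <- NA                  # fixation without diameter
  readr::write_tsv(out, path)
  expect_warning(back <- read_event_report(path), "2 malformed")
  expect_equal(nrow(back), 1)
  expect_equal(attr(back, "n_malformed"), 2L)
})

test_that("AOI files round-trip and enforce the per-modality region counts", {
  aoi <- dplyr::bind_rows(make_aoi("v1", "full"), make_aoi("v1", "single"))
  class(aoi) <- c("pupil_aoi", class(aoi))
  path <- withr::local_tempfile(fileext = ".json")
  write_aoi_set(aoi, path)
  back <- read_aoi_set(path)
  expect_equal(sum(back$modality == "full"), 3)
  expect_equal(sum(back$modality == "single"), 2)
  expect_equal(
    dplyr::arrange(as.data.frame(back), modality, priority),
    dplyr::arrange(as.data.frame(aoi), modality, priority)
  )

  bad <- make_aoi("v1", "full")
  bad$x1[1] <- bad$frame_x1[1] + 10      # region outside the frame
  expect_error(validate_aoi(bad), "outside the frame")

  two <- make_aoi("v1", "full")[1:2, ]   # full modality must have 3 regions
  expect_error(validate_aoi(two), "3 regions")
})

test_that("quality filter excludes subjects above the bad-time threshold", {
  # subject A: 10% of time blinking -> excluded; subject B clean -> kept
  mk_subj <- function(id, blink_ms) {
    fix <- make_regular_stream(25, subject_id = id)   # fixations end at 9.9 s
    if (blink_ms > 0) {
      bl <- make_events(subject_id = id,
                        blink = tibble::tibble(start = 9900, end = 9900 + blink_ms))
      fix <- dplyr::bind_rows(fix, bl)
    }
    fix
  }
  ev <- dplyr::bind_rows(mk_subj("sA", 1000), mk_subj("sB", 0))
  class(ev) <- c("pupil_events", class(ev))
  dur <- tibble::tibble(subject_id = c("sA", "sB"), video_id = "v1",
                        duration_ms = 10000)
  qf <- quality_filter(ev, frame_rect = c(0, 0, 1000, 1000),
                       stream_duration_ms = dur)
  expect_equal(qf$excluded_subjects, "sA")
  expect_true(all(qf$kept$subject_id == "sB"))
  expect_match(qf$summary$reason[qf$summary$subject_id == "sA"], "> 0.060")
})

test_that("the 6% boundary is strict: 5.9% kept, 6.1% excluded", {
  mk <- function(id, bad_ms) {
    ev <- dplyr::bind_rows(
      make_regular_stream(10, subject_id = id),
      make_events(subject_id = id,
                  blink = tibble::tibble(start = 5000, end = 5000 + bad_ms))
    )
    class(ev) <- c("pupil_events", class(ev))
    ev
  }
  dur <- function(id) tibble::tibble(subject_id = id, video_id = "v1",
                                     duration_ms = 100000)
  qf_lo <- quality_filter(mk("s59", 5900), frame_rect = c(0, 0, 1000, 1000),
                          stream_duration_ms = dur("s59"))
  qf_hi <- quality_filter(mk("s61", 6100), frame_rect = c(0, 0, 1000, 1000),
                          stream_duration_ms = dur("s61"))
  expect_length(qf_lo$excluded_subjects, 0)
  expect_equal(qf_hi$excluded_subjects, "s61")
})

test_that("out-of-frame fixation time counts toward the bad fraction", {
  ev <- make_regular_stream(10, x = 2000, y = 2000)  # all outside frame
  dur <- tibble::tibble(subject_id = "s1", video_id = "v1", duration_ms = 10000)
  qf <- quality_filter(ev, frame_rect = c(0, 0, 1000, 1000),
                       stream_duration_ms = dur)
  expect_equal(qf$excluded_subjects, "s1")
  expect_equal(qf$summary$offframe_ms, 10 * 300)
})

test_that("adding blink time never re-includes an excluded subject", {
  base_blink <- 7000
  for (extra in c(0, 1000, 5000, 20000)) {
    ev <- dplyr::bind_rows(
      make_regular_stream(10),
      make_events(blink = tibble::tibble(start = 50000,
                                         end = 50000 + base_blink + extra))
    )
    class(ev) <- c("pupil_events", class(ev))
    dur <- tibble::tibble(subject_id = "s1", video_id = "v1",
                          duration_ms = 100000)
    qf <- quality_filter(ev, frame_rect = c(0, 0, 1000, 1000),
                         stream_duration_ms = dur)
    expect_equal(qf$excluded_subjects, "s1")
  }
})

test_that("zero-duration recordings are rejected", {
  ev <- make_regular_stream(3)
  dur <- tibble::tibble(subject_id = "s1", video_id = "v1", duration_ms = 0)
  expect_error(
    quality_filter(ev, frame_rect = c(0, 0, 1000, 1000),
                   stream_duration_ms = dur),
    "zero-duration"
  )
})
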