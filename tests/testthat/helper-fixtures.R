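# Shared fixtures, built in code. Heavy objects (the default synthetic
# benchmark and trained models) are memoized so several test files can use
# them without regenerating.

.pf_cache <- new.env(parent = emptyenv())

pf_cached <- function(key, expr) {
  if (!exists(key, envir = .pf_cache, inherits = FALSE)) {
    assign(key, force(expr), envir = .pf_cache)
  }
  get(key, envir = .pf_cache)
}

# a handmade events table: deterministic, tiny
make_events <- function(subject_id = "s1", video_id = "v1", modality = "full",
                        fix = NULL, sacc = NULL, blink = NULL) {
  row <- function(type, start, end, x = NA, y = NA, ex = NA, ey = NA, p = NA) {
    tibble::tibble(subject_id = subject_id, video_id = video_id,
                   modality = modality, event_type = type,
                   start_ms = start, end_ms = end, x_px = x, y_px = y,
                   end_x_px = ex, end_y_px = ey, pupil_um = p)
  }
  parts <- list()
  if (!is.null(fix)) {
    parts$fix <- purrr::pmap_dfr(fix, function(start, end, x, y, p) {
      row("FIX", start, end, x, y, p = p)
    })
  }
  if (!is.null(sacc)) {
    parts$sacc <- purrr::pmap_dfr(sacc, function(start, end, ...) {
      row("SACC", start, end, x = 10, y = 10, ex = 20, ey = 20)
    })
  }
  if (!is.null(blink)) {
    parts$blink <- purrr::pmap_dfr(blink, function(start, end) {
      row("BLINK", start, end)
    })
  }
  if (length(parts) == 0) {
    ev <- row("FIX", 0, 1)[0, ]
  } else {
    ev <- dplyr::arrange(dplyr::bind_rows(parts), start_ms)
  }
  ev$duration_ms <- ev$end_ms - ev$start_ms
  class(ev) <- c("pupil_events", class(ev))
  ev
}

# a regular fixation-only stream: one fixation every `step_ms`, constant or
# supplied diameters
make_regular_stream <- function(n_fix, step_ms = 400, dur_ms = 300,
                                pupil = 2000, x = 500, y = 500, ...) {
  starts <- (seq_len(n_fix) - 1) * step_ms
  make_events(
    fix = tibble::tibble(start = starts, end = starts + dur_ms,
                         x = rep_len(x, n_fix), y = rep_len(y, n_fix),
                         p = rep_len(pupil, n_fix)),
    ...
  )
}

# one-entry AOI table on a 1000 x 1000 frame
make_aoi <- function(video_id = "v1", modality = "full") {
  if (modality == "full") {
    aoi <- tibble::tibble(
      video_id = video_id, modality = modality,
      name = c("INSTRUCTOR", "TEXT", "IMAGE"),
      x0 = c(600, 50, 50), y0 = c(100, 50, 500),
      x1 = c(950, 500, 500), y1 = c(900, 450, 950),
      priority = 1:3
    )
  } else {
    aoi <- tibble::tibble(
      video_id = video_id, modality = modality,
      name = c("TEXT", "IMAGE"),
      x0 = c(50, 50), y0 = c(50, 500),
      x1 = c(500, 500), y1 = c(450, 950),
      priority = 1:2
    )
  }
  aoi$frame_x0 <- 0; aoi$frame_y0 <- 0
  aoi$frame_x1 <- 1000; aoi$frame_y1 <- 1000
  class(aoi) <- c("pupil_aoi", class(aoi))
  aoi
}

# random valid event streams for round-trip property tests
random_stream <- function(subject_id, video_id, n_fix = 5, seed = 1) {
  set.seed(seed)
  starts <- cumsum(runif(n_fix, 100, 500))
  ends <- starts + runif(n_fix, 50, 90)
  make_events(
    subject_id = subject_id, video_id = video_id,
    modality = sample(c("full", "dual", "single"), 1),
    fix = tibble::tibble(start = starts, end = ends,
                         x = runif(n_fix, 0, 1000), y = runif(n_fix, 0, 1000),
                         p = runif(n_fix, 1500, 3000)),
    sacc = tibble::tibble(start = ends + 1, end = ends + 20),
    blink = tibble::tibble(start = starts + 2000 + 5000 * seq_len(n_fix),
                           end = starts + 2150 + 5000 * seq_len(n_fix))
  )
}

# a small synthetic study for structural tests (seconds, not minutes)
tiny_study <- function() {
  pf_cached("tiny_study", generate_study(synth_config(n_subjects = 6, seed = 11)))
}

tiny_blocks <- function() {
  pf_cached("tiny_blocks", {
    st <- tiny_study()
    qf <- quality_filter(st$events, st$aoi,
                         stream_duration_ms = st$stream_duration_ms)
    segment_blocks(qf$kept, duration_ms = st$stream_duration_ms)
  })
}

# Regular-geometry blocks for the affine-recovery check: every block has
# the same fixation count, so the input-mean is an exact linear functional
# of the padded feature matrix and ridge regression can recover an affine
# label map to numerical precision.
regular_affine_blocks <- function(n_streams = 300, seed = 45) {
  pf_cached("regular_affine_blocks", {
    ev <- purrr::map_dfr(seq_len(n_streams), function(i) {
      diams <- pupilflow:::with_seed(seed + i, rnorm(38, 2100, 100))
      make_regular_stream(38, step_ms = 800, dur_ms = 600, pupil = diams,
                          subject_id = sprintf("r%03d", i))
    })
    class(ev) <- c("pupil_events", class(ev))
    blocks <- segment_blocks(ev, block_s = 15, input_s = 10,
                             duration_ms = 30400)
    blocks$label_um <- 0.5 * blocks$input_mean_um + 100
    blocks
  })
}

# the default synthetic benchmark (60 subjects); shared by the acceptance
# tests and the generator-scale checks
benchmark_study <- function() {
  pf_cached("benchmark_study", generate_study(synth_config(n_subjects = 60, seed = 1)))
}

benchmark_blocks <- function() {
  pf_cached("benchmark_blocks", {
    st <- benchmark_study()
    qf <- quality_filter(st$events, st$aoi,
                         stream_duration_ms = st$stream_duration_ms)
    segment_blocks(qf$kept, duration_ms = st$stream_duration_ms)
  })
}

# Benchmark-scale training profiles. The cheap profile is for the model
# orderings, where the margins are large; the residual profile (wider
# network, longer patience, four pooled runs) is for the per-subject
# residual analyses, where the decomposition quality matters.
bench_lstm_spec <- function(featureset, runs = 1) {
  experiment_spec(
    model_config("LSTM", profile = "fast", epochs = 60,
                 early_stopping_patience = 20),
    featureset, runs = runs, seed = fanout_seed(1, 9L)
  )
}

bench_residual_spec <- function(featureset, runs = 4) {
  experiment_spec(
    model_config("LSTM", profile = "fast", epochs = 150, hidden_units = 32,
                 early_stopping_patience = 40),
    featureset, runs = runs, seed = fanout_seed(1, 9L)
  )
}

bench_lstm_experiment <- function(key, featureset, spec_fn = bench_lstm_spec) {
  pf_cached(key, {
    st <- benchmark_study()
    experiment_rmse(benchmark_blocks(), spec_fn(featureset), aoi = st$aoi)
  })
}
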