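#' Configure a synthetic eye-tracking study
#'
#' The generator emulates the structure of an instructional-video viewing
#' study: subjects watch several 300-s videos in one of three presentation
#' modalities while fixations, saccades and blinks are recorded. The pupil
#' signal has a known decomposition
#' `pupil = baseline - lum_gain * L(t) + arousal_gain * A(t) + noise`,
#' where `L` is the scene luminance low-pass filtered with a 1-s time
#' constant (the pupil constricts with increasing luminance) and `A` is a
#' sum of non-negative, exponentially decaying dilation pulses whose rate
#' grows with a latent per-subject engagement `e`. Engagement also drives
#' the post-viewing assessment score, `score = clip(0.15 + 0.7 e + noise)`,
#' so the arousal-driven pupil component and performance share a common
#' cause while the luminance-driven component does not.
#'
#' Scene luminance levels are uniform on (0, 1) with scene lengths uniform
#' on 5-20 s. The on-screen "active" area of interest follows the scene
#' script (bright scenes highlight slide text, dark scenes images,
#' intermediate ones the instructor where present), so AOI occupancy
#' carries luminance information without any explicit luminance input
#' channel.
#'
#' @param n_subjects Number of subjects (default 60).
#' @param n_videos Videos per subject (default 3).
#' @param video_s Video length in seconds (default 300).
#' @param baseline_mean,baseline_sd Per-subject baseline pupil diameter
#'   (micrometres), Normal(2100, 300).
#' @param lum_gain Luminance gain in micrometres (constrictive, default
#'   600).
#' @param arousal_gain Dilation-pulse amplitude in micrometres (default
#'   250).
#' @param pulse_rate_base,pulse_rate_slope Pulse rate per second:
#'   `base * (1 + slope * engagement)` (defaults 0.05 and 4).
#' @param pulse_decay_s Pulse exponential-decay time constant (default 2).
#' @param lum_tau_s Luminance low-pass time constant (default 1).
#' @param noise_sd Measurement noise SD in micrometres (default 60).
#' @param scene_s Scene-length range in seconds (default `c(5, 20)`).
#' @param fix_dur_median_ms,fix_dur_sdlog Log-normal fixation durations
#'   (median 250 ms).
#' @param sacc_gap_ms Inter-fixation saccade duration range.
#' @param blink_rate Blink rate per second (default 0.2).
#' @param blink_dur_ms Blink duration range.
#' @param aoi_attract Probability that a fixation lands inside the active
#'   AOI (default 0.8).
#' @param score_intercept,score_slope,score_noise Score model parameters.
#' @param pupil_floor_um Hard floor on emitted diameters (default 300).
#' @param seed Master seed.
#' @return An object of class `pupil_synth_config`.
#' @export
synth_config <- function(n_subjects = 60, n_videos = 3, video_s = 300,
                         baseline_mean = 2100, baseline_sd = 300,
                         lum_gain = 600, arousal_gain = 250,
                         pulse_rate_base = 0.05, pulse_rate_slope = 4,
                         pulse_decay_s = 2, lum_tau_s = 1,
                         noise_sd = 60, scene_s = c(5, 20),
                         fix_dur_median_ms = 250, fix_dur_sdlog = 0.4,
                         sacc_gap_ms = c(20, 80), blink_rate = 0.2,
                         blink_dur_ms = c(100, 300), aoi_attract = 0.8,
                         score_intercept = 0.15, score_slope = 0.7,
                         score_noise = 0.07, pupil_floor_um = 300,
                         seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_subjects >= 1, n_videos >= 1, video_s > 0,
            lum_gain >= 0, arousal_gain >= 0, noise_sd >= 0,
            pulse_decay_s > 0, lum_tau_s > 0, blink_rate >= 0,
            pupil_floor_um > 0)
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pupil_synth_config")
}

# default AOI layout on a 1920 x 1080 frame
default_aoi_layout <- function(video_ids) {
  purrr::map_dfr(video_ids, function(v) {
    dplyr::bind_rows(
      tibble::tibble(video_id = v, modality = "full",
                     name = c("INSTRUCTOR", "TEXT", "IMAGE"),
                     x0 = c(1280, 100, 100), y0 = c(200, 100, 560),
                     x1 = c(1800, 900, 900), y1 = c(900, 500, 960),
                     priority = 1:3),
      purrr::map_dfr(c("dual", "single"), function(m) {
        tibble::tibble(video_id = v, modality = m,
                       name = c("TEXT", "IMAGE"),
                       x0 = c(160, 160), y0 = c(100, 560),
                       x1 = c(1100, 1100), y1 = c(520, 980),
                       priority = 1:2)
      })
    )
  }) |>
    dplyr::mutate(frame_x0 = 0, frame_y0 = 0, frame_x1 = 1920, frame_y1 = 1080) |>
    (\(x) { class(x) <- c("pupil_aoi", class(x)); x })()
}

# piecewise-constant scene timeline for one video (shared across subjects)
generate_timeline <- function(config, video_id, vidx) {
  with_seed(fanout_seed(config$seed, 101L, vidx), {
    starts <- numeric(0)
    t <- 0
    while (t < config$video_s) {
      starts <- c(starts, t)
      t <- t + runif(1, config$scene_s[1], config$scene_s[2])
    }
    tibble::tibble(
      video_id = video_id,
      start_s = starts,
      end_s = c(starts[-1], config$video_s),
      lum = runif(length(starts))
    )
  })
}

# the scene script highlights different screen regions by brightness
active_aoi_for <- function(lum, modality) {
  ifelse(lum >= 2 / 3, "TEXT",
         ifelse(lum < 1 / 3, "IMAGE",
                ifelse(modality == "full", "INSTRUCTOR", "TEXT")))
}

# exponential low-pass of the piecewise-constant luminance, evaluated at
# times t (seconds); closed form per scene segment
filtered_luminance <- function(timeline, tau, t) {
  k <- nrow(timeline)
  l_at_start <- numeric(k)
  l_at_start[1] <- timeline$lum[1]  # start at steady state of scene 1
  if (k > 1) {
    for (i in 2:k) {
      dt <- timeline$end_s[i - 1] - timeline$start_s[i - 1]
      l_at_start[i] <- timeline$lum[i - 1] +
        (l_at_start[i - 1] - timeline$lum[i - 1]) * exp(-dt / tau)
    }
  }
  idx <- findInterval(t, timeline$start_s)
  idx[idx < 1] <- 1
  timeline$lum[idx] +
    (l_at_start[idx] - timeline$lum[idx]) * exp(-(t - timeline$start_s[idx]) / tau)
}

#' Generate one synthetic eye-tracking stream
#'
#' Tiles the video timeline with alternating fixations and saccades, adds
#' blinks as a Poisson process, places fixations inside the scene's active
#' AOI with probability `aoi_attract` (uniformly in the frame otherwise),
#' and emits per-fixation pupil diameters from the configured luminance +
#' arousal + noise model. Deterministic for a fixed seed.
#'
#' @param config A [synth_config()].
#' @param subject_id,video_id,modality Stream identity.
#' @param timeline Scene timeline from the study generator.
#' @param aoi AOI table covering this (video, modality).
#' @param baseline_um Subject baseline diameter.
#' @param engagement Latent engagement in `[0, 1]`.
#' @param seed Stream seed.
#' @return A list with `events` (the stream's event rows) and `truth`
#'   (per-fixation decomposition: `lum_um`, `arousal_um`, `noise_um`).
#' @export
generate_stream <- function(config, subject_id, video_id, modality,
                            timeline, aoi, baseline_um, engagement, seed) {
  with_seed(seed, {
    video_ms <- config$video_s * 1000
    # fixation / saccade tiling
    fs <- list(); t <- 0
    repeat {
      dur <- rlnorm(1, log(config$fix_dur_median_ms), config$fix_dur_sdlog)
      if (t + dur > video_ms) break
      gap <- runif(1, config$sacc_gap_ms[1], config$sacc_gap_ms[2])
      fs[[length(fs) + 1]] <- c(t, t + dur, min(t + dur + gap, video_ms))
      t <- t + dur + gap
      if (t >= video_ms) break
    }
    fm <- do.call(rbind, fs)
    n_fix <- nrow(fm)
    # positions: active AOI attraction
    mid_s <- (fm[, 1] + fm[, 2]) / 2000
    scene_idx <- pmax(findInterval(mid_s, timeline$start_s), 1)
    act <- active_aoi_for(timeline$lum[scene_idx], modality)
    fr <- frame_rect_for(aoi, video_id, modality)
    x <- runif(n_fix, fr[1], fr[3]); y <- runif(n_fix, fr[2], fr[4])
    in_aoi <- runif(n_fix) < config$aoi_attract
    for (i in which(in_aoi)) {
      r <- aoi[aoi$video_id == video_id & aoi$modality == modality &
                 aoi$name == act[i], , drop = FALSE]
      if (nrow(r) == 1) {
        x[i] <- runif(1, r$x0, r$x1 - 1e-6)
        y[i] <- runif(1, r$y0, r$y1 - 1e-6)
      }
    }
    # pupil model at fixation midpoints
    lum <- filtered_luminance(timeline, config$lum_tau_s, mid_s)
    rate <- config$pulse_rate_base * (1 + config$pulse_rate_slope * engagement)
    n_pulse <- rpois(1, rate * config$video_s)
    pulse_t <- sort(runif(n_pulse, 0, config$video_s))
    arousal <- vapply(mid_s, function(tt) {
      past <- pulse_t[pulse_t <= tt]
      sum(exp(-(tt - past) / config$pulse_decay_s))
    }, numeric(1))
    noise <- rnorm(n_fix, 0, config$noise_sd)
    lum_um <- -config$lum_gain * lum
    arousal_um <- config$arousal_gain * arousal
    pupil <- pmax(baseline_um + lum_um + arousal_um + noise,
                  config$pupil_floor_um)

    fix <- tibble::tibble(
      subject_id = subject_id, video_id = video_id, modality = modality,
      event_type = "FIX", start_ms = fm[, 1], end_ms = fm[, 2],
      x_px = x, y_px = y, end_x_px = NA_real_, end_y_px = NA_real_,
      pupil_um = pupil
    )
    has_gap <- fm[, 3] > fm[, 2]
    sacc <- tibble::tibble(
      subject_id = subject_id, video_id = video_id, modality = modality,
      event_type = "SACC",
      start_ms = fm[has_gap, 2], end_ms = fm[has_gap, 3],
      x_px = x[has_gap], y_px = y[has_gap],
      end_x_px = c(x[-1], x[n_fix])[has_gap],
      end_y_px = c(y[-1], y[n_fix])[has_gap],
      pupil_um = NA_real_
    )
    n_blink <- rpois(1, config$blink_rate * config$video_s)
    bs <- sort(runif(n_blink, 0, video_ms))
    bd <- runif(n_blink, config$blink_dur_ms[1], config$blink_dur_ms[2])
    be <- pmin(bs + bd, video_ms)
    keep <- rep(TRUE, n_blink)  # drop overlapping blinks
    if (n_blink > 1) for (i in 2:n_blink) if (bs[i] < max(be[seq_len(i - 1)][keep[seq_len(i - 1)]], -Inf)) keep[i] <- FALSE
    blink <- tibble::tibble(
      subject_id = subject_id, video_id = video_id, modality = modality,
      event_type = "BLINK", start_ms = bs[keep], end_ms = be[keep],
      x_px = NA_real_, y_px = NA_real_, end_x_px = NA_real_,
      end_y_px = NA_real_, pupil_um = NA_real_
    )
    events <- dplyr::bind_rows(fix, sacc, blink) |>
      dplyr::arrange(.data$start_ms)
    events$duration_ms <- events$end_ms - events$start_ms
    truth <- tibble::tibble(
      subject_id = subject_id, video_id = video_id, modality = modality,
      fix_start_ms = fm[, 1],
      lum_um = lum_um, arousal_um = arousal_um, noise_um = noise,
      pupil_um = pupil, baseline_um = baseline_um
    )
    list(events = events, truth = truth)
  })
}

#' Generate a complete synthetic study
#'
#' Draws per-subject baselines and engagements, assigns modalities,
#' generates one stream per subject and video, and produces assessment
#' scores from the engagement-driven score model. Fully deterministic for a
#' fixed config seed.
#'
#' @param config A [synth_config()].
#' @return A list of class `pupil_synth_study`: `events` (all streams,
#'   a `pupil_events` tibble), `aoi`, `scores` (`subject_id`, `modality`,
#'   `score`), `subjects` (latents: `baseline_um`, `engagement`),
#'   `truth` (per-fixation decomposition), `timelines`, and
#'   `stream_duration_ms`.
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "pupil_synth_config"))
  video_ids <- paste0("video", seq_len(config$n_videos))
  subject_ids <- sprintf("s%02d", seq_len(config$n_subjects))
  aoi <- default_aoi_layout(video_ids)
  timelines <- purrr::map(seq_along(video_ids),
                          function(v) generate_timeline(config, video_ids[v], v))
  names(timelines) <- video_ids
  subjects <- with_seed(fanout_seed(config$seed, 1L), {
    tibble::tibble(
      subject_id = subject_ids,
      modality = sample(rep(.MODALITIES, length.out = config$n_subjects)),
      baseline_um = rnorm(config$n_subjects, config$baseline_mean,
                          config$baseline_sd),
      engagement = rbeta(config$n_subjects, 2, 2)
    )
  })
  scores <- with_seed(fanout_seed(config$seed, 2L), {
    tibble::tibble(
      subject_id = subjects$subject_id,
      modality = subjects$modality,
      score = pmin(pmax(config$score_intercept +
                          config$score_slope * subjects$engagement +
                          rnorm(config$n_subjects, 0, config$score_noise),
                        0), 1)
    )
  })
  streams <- purrr::map(seq_len(config$n_subjects), function(i) {
    purrr::map(seq_along(video_ids), function(v) {
      generate_stream(
        config, subjects$subject_id[i], video_ids[v], subjects$modality[i],
        timelines[[v]], aoi, subjects$baseline_um[i], subjects$engagement[i],
        seed = fanout_seed(config$seed, 1000L + i, v)
      )
    })
  })
  events <- dplyr::bind_rows(purrr::map(streams, \(s) purrr::map_dfr(s, "events")))
  class(events) <- c("pupil_events", class(events))
  truth <- dplyr::bind_rows(purrr::map(streams, \(s) purrr::map_dfr(s, "truth")))
  durations <- events |>
    dplyr::distinct(.data$subject_id, .data$video_id) |>
    dplyr::mutate(duration_ms = config$video_s * 1000)
  structure(
    list(events = events, aoi = aoi, scores = scores, subjects = subjects,
         truth = truth, timelines = timelines,
         stream_duration_ms = durations, config = config),
    class = "pupil_synth_study"
  )
}

#' Write a synthetic study to disk
#'
#' Serializes the study through the package's own writers: the event report
#' (TSV), the AOI definition (JSON), the score table (CSV) and the
#' synthetic truth bundle (JSON).
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_event_report(study$events, file.path(dir, "events.tsv"))
  write_aoi_set(study$aoi, file.path(dir, "aoi.json"))
  write_scores(study$scores, file.path(dir, "scores.csv"))
  jsonlite::write_json(
    list(subjects = study$subjects, truth = study$truth,
         config = unclass(study$config)),
    file.path(dir, "truth.json"), digits = NA
  )
  invisible(dir)
}
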