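#' Configure an end-to-end pipeline run
#'
#' @param events_path,aoi_path,scores_path Input files (an event report,
#'   an AOI definition, a score table). Leave `NULL` and set `simulate`
#'   to generate a synthetic study instead.
#' @param simulate Optional [synth_config()]; when given, inputs are
#'   generated rather than read.
#' @param out_dir Output directory for metrics and artifacts.
#' @param block_s,input_s Block geometry in seconds.
#' @param models Character vector of model types to evaluate.
#' @param featureset A [feature_set()] used for all models.
#' @param runs Runs per experiment.
#' @param profile Model profile, `"reference"` or `"fast"`.
#' @param residual_model Model whose residuals feed the performance
#'   analyses (default `"LSTM"` if listed, else the first model).
#' @param n_perm Label permutations for the AUC null.
#' @param video_s Recording length per stream in seconds (used when
#'   reading event files, where true duration is not stored).
#' @param seed Master seed.
#' @return An object of class `pupil_pipeline_config`.
#' @export
pipeline_config <- function(events_path = NULL, aoi_path = NULL,
                            scores_path = NULL, simulate = NULL,
                            out_dir = tempfile("pupilflow-run-"),
                            block_s = 15, input_s = 10,
                            models = c("INPUT_MEAN", "LSTM"),
                            featureset = feature_set(diameter = TRUE, aoi = TRUE),
                            runs = 1, profile = "fast",
                            residual_model = NULL, n_perm = 10000,
                            video_s = 300, seed = 1L) {
  if (!(block_s > input_s)) stop_pf("block_s must exceed input_s")
  models <- vapply(models, function(m) match.arg(toupper(m), .MODEL_TYPES), "")
  structure(
    list(events_path = events_path, aoi_path = aoi_path,
         scores_path = scores_path, simulate = simulate, out_dir = out_dir,
         block_s = block_s, input_s = input_s, models = unname(models),
         featureset = featureset, runs = runs, profile = profile,
         residual_model = residual_model %||%
           (if ("LSTM" %in% models) "LSTM" else models[1]),
         n_perm = n_perm, video_s = video_s, seed = as.integer(seed)),
    class = "pupil_pipeline_config"
  )
}

#' Run the full prediction-and-residual pipeline
#'
#' Executes quality filtering, block segmentation, the repeated-split RMSE
#' experiment for each requested model, and — when scores are available —
#' the performance-group comparison, per-subject residual correlations and
#' tertile ROC/AUC with a permutation null, for the configured residual
#' model. Metrics are written as JSON plus CSV side tables under
#' `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return The metrics list, invisibly classed `pupil_metrics`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pupil_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_msg <- function(...) message("[pupilflow] ", sprintf(...))

  if (!is.null(config$simulate)) {
    log_msg("simulating study (%d subjects)", config$simulate$n_subjects)
    study <- generate_study(config$simulate)
    events <- study$events; aoi <- study$aoi; scores <- study$scores
    durations <- study$stream_duration_ms
  } else {
    if (is.null(config$events_path) || is.null(config$aoi_path)) {
      stop_pf("stage input: events_path and aoi_path are required without simulate")
    }
    events <- read_event_report(config$events_path)
    aoi <- read_aoi_set(config$aoi_path)
    scores <- NULL
    if (!is.null(config$scores_path)) {
      if (!file.exists(config$scores_path)) {
        stop_pf("stage input: scores file not found: %s", config$scores_path)
      }
      scores <- read_scores(config$scores_path)
    }
    durations <- events |>
      dplyr::distinct(.data$subject_id, .data$video_id) |>
      dplyr::mutate(duration_ms = config$video_s * 1000)
  }

  log_msg("quality filter")
  qf <- quality_filter(events, aoi, stream_duration_ms = durations)
  log_msg("kept %d / %d subjects", dplyr::n_distinct(qf$kept$subject_id),
          nrow(qf$summary))

  log_msg("segmenting %g-s blocks (%g-s input)", config$block_s, config$input_s)
  blocks <- segment_blocks(qf$kept, block_s = config$block_s,
                           input_s = config$input_s, duration_ms = durations)
  log_msg("%d blocks (%d dropped for missing fixations)", nrow(blocks),
          attr(blocks, "n_dropped"))

  experiments <- list()
  for (m in config$models) {
    log_msg("experiment: %s", m)
    cfg <- model_config(m, profile = config$profile,
                        seed = fanout_seed(config$seed, match(m, .MODEL_TYPES)))
    spec <- experiment_spec(cfg, config$featureset, runs = config$runs,
                            seed = config$seed)
    experiments[[m]] <- experiment_rmse(blocks, spec, aoi = aoi)
  }

  metrics <- list(
    config = list(block_s = config$block_s, input_s = config$input_s,
                  output_s = config$block_s - config$input_s,
                  features = format(config$featureset), runs = config$runs,
                  profile = config$profile, seed = config$seed),
    quality = qf$summary,
    n_blocks = nrow(blocks),
    models = purrr::imap(experiments, function(e, m) {
      list(model = m, mean_rmse = e$mean_rmse, sd_rmse = e$sd_rmse,
           per_run = e$per_run_rmse)
    })
  )

  if (!is.null(scores)) {
    rm_name <- config$residual_model
    exp_r <- experiments[[rm_name]]
    log_msg("residual analyses on %s", rm_name)
    groups <- split_by_performance(exp_r, scores)
    subj <- residuals_by_subject(exp_r) |>
      dplyr::left_join(scores[, c("subject_id", "score")], by = "subject_id")
    cors <- list(
      residual = spearman_rho(subj$mean_residual_um, subj$score),
      prediction = spearman_rho(subj$mean_prediction_um, subj$score),
      truth = spearman_rho(subj$mean_truth_um, subj$score)
    )
    tg <- tertile_groups(scores[scores$subject_id %in% subj$subject_id, ])
    tsub <- subj[subj$subject_id %in% c(tg$bottom, tg$top), ]
    is_top <- tsub$subject_id %in% tg$top
    perms <- purrr::imap(
      list(residual = tsub$mean_residual_um,
           prediction = tsub$mean_prediction_um,
           truth = tsub$mean_truth_um),
      function(v, nm) permutation_auc_pvalue(
        v, is_top, n_perm = config$n_perm,
        seed = fanout_seed(config$seed, 55L, match(nm, c("residual", "prediction", "truth")))
      )
    )
    metrics$performance <- list(
      residual_model = rm_name,
      threshold = groups$threshold,
      groups = groups,
      subject_aggregates = subj,
      correlations = cors,
      fisher_z_residual_vs_truth = if (cors$residual$n > 3) {
        fisher_z_compare(cors$residual$rho, cors$truth$rho,
                         cors$residual$n, cors$truth$n)
      },
      auc = purrr::map(perms, function(p) {
        list(auc = p$auc, p_value = p$p_value, n_perm = p$n_perm)
      }),
      permutations = perms
    )
  }

  write_metrics(metrics, config$out_dir)
  log_msg("metrics written to %s", config$out_dir)
  invisible(structure(metrics, class = "pupil_metrics"))
}

write_metrics <- function(metrics, out_dir) {
  slim <- list(
    config = metrics$config,
    n_blocks = metrics$n_blocks,
    models = purrr::map(metrics$models, function(m) {
      list(model = m$model, mean_rmse = m$mean_rmse, sd_rmse = m$sd_rmse)
    })
  )
  if (!is.null(metrics$performance)) {
    pf <- metrics$performance
    slim$performance <- list(
      residual_model = pf$residual_model,
      threshold = pf$threshold,
      group_summary = pf$groups$group_summary,
      u_test = pf$groups$u_test[c("U", "p_value")],
      correlations = purrr::map(pf$correlations, function(cc) cc[c("rho", "p_value", "n")]),
      fisher_z = pf$fisher_z_residual_vs_truth,
      auc = pf$auc
    )
    readr::write_csv(pf$subject_aggregates,
                     file.path(out_dir, "subject_aggregates.csv"), progress = FALSE)
  }
  readr::write_csv(metrics$quality, file.path(out_dir, "quality_summary.csv"),
                   progress = FALSE)
  jsonlite::write_json(slim, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(out_dir)
}

#' Render a human-readable metrics report
#'
#' Produces a deterministic markdown summary: a model table (Mean (SD)
#' RMSE), a feature/embedding delta column when paired results are present,
#' and the performance-group and AUC sections when available.
#'
#' @param metrics A `pupil_metrics` object from [run_pipeline()], or the
#'   path to a written `metrics.json`.
#' @return A character scalar of markdown, invisibly; also printed.
#' @export
render_report <- function(metrics) {
  if (is.character(metrics)) {
    if (!file.exists(metrics)) stop_pf("metrics file not found: %s", metrics)
    metrics <- jsonlite::read_json(metrics, simplifyVector = TRUE)
  }
  lines <- c("# pupilflow metrics report", "")
  cfgl <- metrics$config
  lines <- c(lines, sprintf("Blocks: %s s (input %s s, output %s s); features %s; %s run(s).",
                            cfgl$block_s, cfgl$input_s, cfgl$output_s,
                            cfgl$features, cfgl$runs), "")
  lines <- c(lines, "| Model | RMSE (um) |", "|---|---|")
  models <- metrics$models
  if (is.data.frame(models)) models <- purrr::transpose(models)
  for (m in models) {
    lines <- c(lines, sprintf("| %s | %.2f (%.2f) |", m$model, m$mean_rmse, m$sd_rmse))
  }
  pf <- metrics$performance
  if (!is.null(pf)) {
    lines <- c(lines, "", sprintf("## Performance groups (threshold %.3f, model %s)",
                                  pf$threshold, pf$residual_model))
    gs <- if (!is.null(pf$groups)) pf$groups$group_summary else pf$group_summary
    lines <- c(lines, "", "| Group | RMSE (um) | blocks/run |", "|---|---|---|")
    for (i in seq_len(nrow(gs))) {
      lines <- c(lines, sprintf("| %s | %.2f (%.2f) | %.0f |",
                                gs$group[i], gs$mean_rmse[i], gs$sd_rmse[i],
                                gs$mean_n[i]))
    }
    ut <- if (!is.null(pf$groups)) pf$groups$u_test else pf$u_test
    if (!is.null(ut)) {
      lines <- c(lines, "", sprintf("Mann-Whitney U = %.1f, p = %.4g.", ut$U, ut$p_value))
    }
    cors <- pf$correlations
    lines <- c(lines, "", "## Subject-level correlations with performance", "",
               "| Measure | Spearman rho | p |", "|---|---|---|")
    for (nm in names(cors)) {
      lines <- c(lines, sprintf("| %s | %.3f | %.4g |", nm, cors[[nm]]$rho,
                                cors[[nm]]$p_value))
    }
    lines <- c(lines, "", "## Tertile AUC (permutation null)", "",
               "| Measure | AUC | p |", "|---|---|---|")
    for (nm in names(pf$auc)) {
      lines <- c(lines, sprintf("| %s | %.3f | %.4g |", nm, pf$auc[[nm]]$auc,
                                pf$auc[[nm]]$p_value))
    }
  } else {
    lines <- c(lines, "", "_No performance scores supplied; group and AUC sections omitted._")
  }
  txt <- paste(lines, collapse = "\n")
  cat(txt, "\n")
  invisible(txt)
}
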