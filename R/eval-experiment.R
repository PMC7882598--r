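#' Specify a repeated-split prediction experiment
#'
#' An experiment is defined by the model type `M`, the input feature set
#' `I`, the block geometry (whose output length is `O = block_s - input_s`),
#' and the number of independent random train/validation/test splits (runs)
#' over which the test RMSE is averaged. Blocks are pooled across subjects,
#' videos and modalities and treated as independent samples.
#'
#' @param config A [model_config()].
#' @param featureset A [feature_set()].
#' @param runs Number of random splits (default 10).
#' @param train_frac,val_frac,test_frac Split fractions (must sum to 1).
#' @param seed Master seed; per-run seeds are fanned out deterministically.
#' @return An object of class `pupil_experiment_spec`.
#' @export
experiment_spec <- function(config, featureset, runs = 10,
                            train_frac = 0.7, val_frac = 0.1,
                            test_frac = 0.2, seed = 1L) {
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-9) {
    stop_pf("split fractions must sum to 1")
  }
  if (runs < 1) stop_pf("runs must be >= 1")
  structure(
    list(config = config, featureset = featureset, runs = as.integer(runs),
         train_frac = train_frac, val_frac = val_frac, test_frac = test_frac,
         seed = as.integer(seed)),
    class = "pupil_experiment_spec"
  )
}

# deterministic block-level split for one run
split_blocks <- function(n, spec, run) {
  idx <- with_seed(fanout_seed(spec$seed, run), sample.int(n))
  n_tr <- floor(spec$train_frac * n)
  n_val <- floor(spec$val_frac * n)
  if (n_tr < 2 || n_val < 1 || n - n_tr - n_val < 1) {
    stop_pf("too few blocks (%d) to fill train/validation/test splits", n)
  }
  list(train = idx[seq_len(n_tr)],
       val = idx[seq(n_tr + 1, n_tr + n_val)],
       test = idx[seq(n_tr + n_val + 1, n)])
}

#' Run a repeated-split RMSE experiment
#'
#' For each run, the pooled blocks are split at block level into
#' train/validation/test with a run-specific seed, the model is trained,
#' test blocks are predicted, and the test RMSE is recorded. The summary is
#' the mean and SD of the per-run RMSEs (the "Mean (SD)" convention).
#'
#' @param blocks Pooled `pupil_blocks` (all subjects, videos, modalities).
#' @param spec An [experiment_spec()].
#' @param aoi AOI tibble (required when the feature set includes AOI).
#' @return An object of class `pupil_experiment`: `mean_rmse`, `sd_rmse`,
#'   `per_run_rmse`, and `runs` — a tibble with one row per test block and
#'   run, carrying `truth_um`, `prediction_um` and
#'   `residual_um = truth_um - prediction_um`.
#' @export
experiment_rmse <- function(blocks, spec, aoi = NULL) {
  stopifnot(inherits(spec, "pupil_experiment_spec"))
  n <- nrow(blocks)
  run_out <- purrr::map(seq_len(spec$runs), function(r) {
    sp <- split_blocks(n, spec, r)
    cfg <- spec$config
    cfg$seed <- fanout_seed(spec$seed, r, 7L)
    model <- train_model(cfg, blocks[sp$train, ], blocks[sp$val, ],
                         spec$featureset, aoi = aoi)
    test <- blocks[sp$test, ]
    pred <- predict(model, test)
    tibble::tibble(
      run = r,
      block_row = sp$test,
      subject_id = test$subject_id,
      video_id = test$video_id,
      modality = test$modality,
      block_id = test$block_id,
      truth_um = test$label_um,
      prediction_um = pred,
      residual_um = test$label_um - pred
    )
  })
  runs <- dplyr::bind_rows(run_out)
  per_run <- runs |>
    dplyr::group_by(.data$run) |>
    dplyr::summarise(rmse = rmse(.data$prediction_um, .data$truth_um),
                     n = dplyr::n(), .groups = "drop")
  structure(
    list(spec = spec,
         mean_rmse = mean(per_run$rmse),
         sd_rmse = if (nrow(per_run) > 1) sd(per_run$rmse) else 0,
         per_run_rmse = per_run,
         runs = runs),
    class = "pupil_experiment"
  )
}

#' @export
print.pupil_experiment <- function(x, ...) {
  cat(sprintf("<pupil_experiment> %s, features %s: RMSE %.2f (%.2f) um over %d run(s)\n",
              x$spec$config$model, format(x$spec$featureset),
              x$mean_rmse, x$sd_rmse, nrow(x$per_run_rmse)))
  invisible(x)
}

#' Compare model error between performance groups
#'
#' Test blocks are split by their subject's assessment score relative to a
#' threshold (default: the mean score over subjects) into "Greater Than
#' Mean" and "Lesser Than Mean" groups. Per-group RMSE is computed per run,
#' and the two groups' per-block squared errors (pooled over runs) are
#' compared with the Mann-Whitney U test. Set `per_run = TRUE` to test the
#' per-run RMSE values instead.
#'
#' @param experiment A [experiment_rmse()] result.
#' @param scores A tibble with `subject_id` and `score`.
#' @param threshold Score threshold; defaults to `mean(scores$score)`.
#' @param per_run Use per-run RMSEs as the test samples instead of pooled
#'   per-block squared errors.
#' @return An object of class `pupil_group_comparison`.
#' @export
split_by_performance <- function(experiment, scores, threshold = NULL,
                                 per_run = FALSE) {
  runs <- experiment$runs
  missing <- setdiff(unique(runs$subject_id), scores$subject_id)
  if (length(missing) > 0) {
    stop_pf("no score for subject(s): %s", paste(missing, collapse = ", "))
  }
  threshold <- threshold %||% mean(scores$score)
  runs <- dplyr::left_join(runs, scores[, c("subject_id", "score")],
                           by = "subject_id") |>
    dplyr::mutate(group = ifelse(.data$score > threshold,
                                 "GreaterThanMean", "LesserThanMean"))
  if (dplyr::n_distinct(runs$group) < 2) {
    warn_pf("all test blocks fall on one side of the threshold (%.3f)", threshold)
  }
  per_group_run <- runs |>
    dplyr::group_by(.data$group, .data$run) |>
    dplyr::summarise(rmse = rmse(.data$prediction_um, .data$truth_um),
                     n = dplyr::n(), .groups = "drop")
  group_summary <- per_group_run |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mean_rmse = mean(.data$rmse),
                     sd_rmse = if (dplyr::n() > 1) sd(.data$rmse) else 0,
                     mean_n = mean(.data$n), .groups = "drop")
  test <- NULL
  if (dplyr::n_distinct(runs$group) == 2) {
    if (per_run) {
      a <- per_group_run$rmse[per_group_run$group == "GreaterThanMean"]
      b <- per_group_run$rmse[per_group_run$group == "LesserThanMean"]
    } else {
      a <- runs$residual_um[runs$group == "GreaterThanMean"]^2
      b <- runs$residual_um[runs$group == "LesserThanMean"]^2
    }
    test <- mann_whitney_u(a, b)
  }
  structure(
    list(threshold = threshold, per_group_run = per_group_run,
         group_summary = group_summary, u_test = test,
         samples = if (per_run) "per-run RMSE" else "per-block squared error"),
    class = "pupil_group_comparison"
  )
}

#' @export
print.pupil_group_comparison <- function(x, ...) {
  cat(sprintf("<pupil_group_comparison> threshold %.3f\n", x$threshold))
  for (i in seq_len(nrow(x$group_summary))) {
    g <- x$group_summary[i, ]
    cat(sprintf("  %-16s RMSE %.2f (%.2f), ~%.0f blocks/run\n",
                g$group, g$mean_rmse, g$sd_rmse, g$mean_n))
  }
  if (!is.null(x$u_test)) {
    cat(sprintf("  Mann-Whitney U = %.1f, p = %.4g (%s)\n",
                x$u_test$U, x$u_test$p_value, x$samples))
  }
  invisible(x)
}

#' Per-subject aggregates of truth, prediction and residual
#'
#' Unweighted means over each subject's test blocks, pooled across runs.
#' Because the residual is truth minus prediction elementwise, the
#' aggregates satisfy `mean_truth = mean_prediction + mean_residual`.
#'
#' @param experiment A [experiment_rmse()] result.
#' @return A tibble with one row per subject appearing in any test split:
#'   `subject_id`, `n_blocks`, `mean_truth_um`, `mean_prediction_um`,
#'   `mean_residual_um`.
#' @export
residuals_by_subject <- function(experiment) {
  experiment$runs |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      n_blocks = dplyr::n(),
      mean_truth_um = mean(.data$truth_um),
      mean_prediction_um = mean(.data$prediction_um),
      mean_residual_um = mean(.data$residual_um),
      .groups = "drop"
    )
}
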