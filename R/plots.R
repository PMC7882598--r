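#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_col
#'   geom_errorbar geom_histogram geom_vline geom_smooth labs theme_minimal
#' @export
ggplot2::autoplot

#' Plot per-run RMSEs of an experiment
#'
#' @param object A `pupil_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.pupil_experiment <- function(object, ...) {
  df <- object$per_run_rmse
  ggplot(df, aes(x = factor(.data$run), y = .data$rmse)) +
    geom_col(fill = "steelblue") +
    labs(x = "run", y = "test RMSE (µm)",
         title = sprintf("%s, %s: %.1f (%.1f) µm",
                         object$spec$config$model,
                         format(object$spec$featureset),
                         object$mean_rmse, object$sd_rmse)) +
    theme_minimal()
}

#' Plot the training history of a recurrent model
#'
#' @param object A `pupil_model` fitted with an LSTM or GRU.
#' @param ... Unused.
#' @return A ggplot of train/validation loss per epoch.
#' @exportS3Method ggplot2::autoplot
autoplot.pupil_model <- function(object, ...) {
  if (!object$config$model %in% c("LSTM", "GRU")) {
    stop_pf("training-history plots exist only for recurrent models")
  }
  df <- tidyr::pivot_longer(object$fit$history, c("train_loss", "val_loss"),
                            names_to = "split", values_to = "loss")
  ggplot(df, aes(x = .data$epoch, y = .data$loss, colour = .data$split)) +
    geom_line() +
    labs(x = "epoch", y = "MSE (normalized label)",
         title = sprintf("%s training history (best epoch %d)",
                         object$config$model, object$fit$best_epoch)) +
    theme_minimal()
}

#' Plot the permutation null of a tertile AUC test
#'
#' @param object A `pupil_permutation`.
#' @param ... Unused.
#' @return A ggplot: null histogram with the observed AUC marked.
#' @exportS3Method ggplot2::autoplot
autoplot.pupil_permutation <- function(object, ...) {
  ggplot(tibble::tibble(auc = object$null_auc), aes(x = .data$auc)) +
    geom_histogram(bins = 40, fill = "grey70") +
    geom_vline(xintercept = object$auc, colour = "firebrick") +
    labs(x = "permuted AUC", y = "count",
         title = sprintf("observed AUC %.3f, p = %.4g", object$auc,
                         object$p_value)) +
    theme_minimal()
}

#' Scatter per-subject residuals against assessment scores
#'
#' @param subject_aggregates Output of [residuals_by_subject()] joined with
#'   a `score` column, or the `subject_aggregates` element of pipeline
#'   metrics.
#' @param measure Which aggregate to plot (`"residual"`, `"prediction"` or
#'   `"truth"`).
#' @return A ggplot.
#' @export
plot_subject_residuals <- function(subject_aggregates,
                                   measure = c("residual", "prediction", "truth")) {
  measure <- match.arg(measure)
  col <- paste0("mean_", measure, "_um")
  assert_cols(subject_aggregates, c(col, "score"), "subject aggregates")
  ggplot(subject_aggregates, aes(x = .data$score, y = .data[[col]])) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE, colour = "firebrick") +
    labs(x = "assessment score", y = sprintf("mean %s (µm)", measure)) +
    theme_minimal()
}
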