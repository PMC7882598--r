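#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trained pupil model
#'
#' For recurrent models, the per-epoch training history; for penalized
#' linear models, the nonzero coefficients at the selected penalty; for
#' other models, a one-row description.
#'
#' @param x A `pupil_model`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.pupil_model <- function(x, ...) {
  if (x$config$model %in% c("LSTM", "GRU")) {
    return(x$fit$history)
  }
  if (x$config$model %in% c("RIDGE", "LASSO")) {
    cf <- as.matrix(predict(x$fit$fit, type = "coefficients", s = x$fit$lambda))
    return(tibble::tibble(term = rownames(cf), estimate = cf[, 1])[cf[, 1] != 0, ])
  }
  tibble::tibble(term = x$config$model, estimate = NA_real_)
}

#' @rdname tidy.pupil_model
#' @exportS3Method generics::glance
glance.pupil_model <- function(x, ...) {
  tibble::tibble(
    model = x$config$model,
    features = format(x$featureset),
    profile = x$config$profile,
    best_epoch = if (!is.null(x$fit$best_epoch)) x$fit$best_epoch else NA_integer_,
    best_val_loss = if (!is.null(x$fit$best_val_loss)) x$fit$best_val_loss else NA_real_
  )
}

#' Tidy a repeated-split experiment
#'
#' @param x A `pupil_experiment`.
#' @param ... Unused.
#' @return `tidy()`: per-run test RMSEs. `glance()`: one row with the mean
#'   and SD RMSE.
#' @exportS3Method generics::tidy
tidy.pupil_experiment <- function(x, ...) x$per_run_rmse

#' @rdname tidy.pupil_experiment
#' @exportS3Method generics::glance
glance.pupil_experiment <- function(x, ...) {
  tibble::tibble(
    model = x$spec$config$model,
    features = format(x$spec$featureset),
    runs = nrow(x$per_run_rmse),
    mean_rmse = x$mean_rmse,
    sd_rmse = x$sd_rmse
  )
}

#' Tidy a performance-group comparison
#'
#' @param x A `pupil_group_comparison`.
#' @param ... Unused.
#' @return `tidy()`: per-group, per-run RMSEs. `glance()`: one row with the
#'   group means and the Mann-Whitney test.
#' @exportS3Method generics::tidy
tidy.pupil_group_comparison <- function(x, ...) x$per_group_run

#' @rdname tidy.pupil_group_comparison
#' @exportS3Method generics::glance
glance.pupil_group_comparison <- function(x, ...) {
  g <- x$group_summary
  wide <- setNames(g$mean_rmse, g$group)
  tibble::tibble(
    rmse_greater = unname(wide["GreaterThanMean"]),
    rmse_lesser = unname(wide["LesserThanMean"]),
    u_statistic = if (!is.null(x$u_test)) x$u_test$U else NA_real_,
    p_value = if (!is.null(x$u_test)) x$u_test$p_value else NA_real_,
    samples = x$samples
  )
}

#' Tidy a permutation AUC test
#'
#' @param x A `pupil_permutation`.
#' @param ... Unused.
#' @return `tidy()`: the null AUC sample. `glance()`: observed AUC and
#'   p-value.
#' @exportS3Method generics::tidy
tidy.pupil_permutation <- function(x, ...) {
  tibble::tibble(permutation = seq_along(x$null_auc), auc = x$null_auc)
}

#' @rdname tidy.pupil_permutation
#' @exportS3Method generics::glance
glance.pupil_permutation <- function(x, ...) {
  tibble::tibble(auc = x$auc, p_value = x$p_value, n_perm = x$n_perm,
                 n_top = x$n_top, n_bottom = x$n_bottom)
}
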