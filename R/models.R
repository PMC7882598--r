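.MODEL_TYPES <- c("INPUT_MEAN", "LINEAR", "RIDGE", "LASSO", "RF", "GBM",
                  "GRU", "LSTM")

#' Configure a pupil-diameter predictor
#'
#' Builds the configuration for one model of the menu: the naive input-mean
#' baseline, (regularized) linear regression, tree ensembles, or a
#' two-layer bidirectional recurrent network (LSTM with recurrent dropout,
#' or GRU without). The default recurrent profile follows the reference
#' protocol (up to 5000 epochs, early stopping with patience 500 on the
#' validation loss, Adam at learning rate 1e-4, 50-dimensional AOI
#' embeddings); `profile = "fast"` scales the network and training budget
#' down for desk-scale CPU work.
#'
#' @param model One of `"INPUT_MEAN"`, `"LINEAR"`, `"RIDGE"`, `"LASSO"`,
#'   `"RF"`, `"GBM"`, `"GRU"`, `"LSTM"`.
#' @param profile `"reference"` (the full training protocol) or `"fast"`.
#' @param epochs,early_stopping_patience,learning_rate,batch_size Training
#'   loop settings for the recurrent models.
#' @param hidden_units Recurrent units per direction.
#' @param embedding_dim Dimension of the learned AOI embedding.
#' @param recurrent_dropout Recurrent-dropout rate (LSTM only; the GRU
#'   variant runs without recurrent dropout).
#' @param seed Seed for weight initialization, shuffling and dropout; fixed
#'   seeds give repeatable training.
#' @param ... Overrides stored verbatim in the config (e.g. `num_trees`,
#'   `nrounds`).
#' @return An object of class `pupil_model_config`.
#' @export
model_config <- function(model = "LSTM", profile = c("reference", "fast"),
                         epochs = NULL, early_stopping_patience = NULL,
                         learning_rate = NULL, batch_size = 64,
                         hidden_units = NULL, embedding_dim = NULL,
                         recurrent_dropout = 0.2, seed = 1L, ...) {
  model <- match.arg(toupper(model), .MODEL_TYPES)
  profile <- match.arg(profile)
  defaults <- if (profile == "reference") {
    list(epochs = 5000L, patience = 500L, lr = 1e-4, hidden = 64L, emb = 50L)
  } else {
    list(epochs = 200L, patience = 25L, lr = 1e-3, hidden = 16L, emb = 8L)
  }
  cfg <- list(
    model = model,
    profile = profile,
    epochs = as.integer(epochs %||% defaults$epochs),
    early_stopping_patience = as.integer(early_stopping_patience %||% defaults$patience),
    learning_rate = learning_rate %||% defaults$lr,
    batch_size = as.integer(batch_size),
    hidden_units = as.integer(hidden_units %||% defaults$hidden),
    embedding_dim = as.integer(embedding_dim %||% defaults$emb),
    recurrent_dropout = if (model == "GRU") 0 else recurrent_dropout,
    seed = as.integer(seed),
    extra = list(...)
  )
  if (cfg$learning_rate <= 0) stop_pf("learning_rate must be positive")
  if (cfg$embedding_dim < 1) stop_pf("embedding_dim must be >= 1")
  structure(cfg, class = "pupil_model_config")
}

#' @export
print.pupil_model_config <- function(x, ...) {
  cat(sprintf("<pupil_model_config> %s (%s profile)\n", x$model, x$profile))
  if (x$model %in% c("LSTM", "GRU")) {
    cat(sprintf("  epochs %d, patience %d, lr %g, batch %d, hidden %d, emb %d, dropout %g\n",
                x$epochs, x$early_stopping_patience, x$learning_rate,
                x$batch_size, x$hidden_units, x$embedding_dim,
                x$recurrent_dropout))
  }
  invisible(x)
}

#' Input-mean baseline prediction
#'
#' The naive estimate: the unweighted mean pupil diameter over the
#' input-window fixations of each block. It depends only on the raw
#' fixation events, never on padding.
#'
#' @param blocks A `pupil_blocks` tibble.
#' @return A numeric vector of predictions in micrometres.
#' @export
input_mean_predict <- function(blocks) {
  vapply(blocks$input_fix, function(fx) mean(fx$pupil_um), numeric(1))
}

#' Train a pupil-diameter predictor
#'
#' Fits the configured model on training blocks. Classical models consume
#' [flatten_for_tabular()] features; penalized models pick their penalty on
#' the validation split; recurrent models are trained by minibatch Adam on
#' the z-scored label with early stopping on the validation loss. The
#' target is z-scored with training statistics and predictions are mapped
#' back to micrometres.
#'
#' @param config A [model_config()].
#' @param train_blocks,val_blocks Disjoint `pupil_blocks` tibbles.
#' @param featureset A [feature_set()].
#' @param aoi AOI tibble (needed when the feature set includes AOI).
#' @param stats Optional pre-fitted [fit_feature_stats()]; fitted on
#'   `train_blocks` when `NULL`.
#' @return An object of class `pupil_model`.
#' @export
train_model <- function(config, train_blocks, val_blocks, featureset,
                        aoi = NULL, stats = NULL) {
  stopifnot(inherits(config, "pupil_model_config"))
  if (config$model != "INPUT_MEAN" && nrow(val_blocks) == 0) {
    stop_pf("an empty validation set is not allowed for model %s", config$model)
  }
  obj <- list(config = config, featureset = featureset, aoi = aoi)
  if (config$model == "INPUT_MEAN") {
    obj$stats <- NULL
    obj$fit <- NULL
    class(obj) <- "pupil_model"
    return(obj)
  }
  stats <- stats %||% fit_feature_stats(train_blocks, featureset)
  obj$stats <- stats
  y <- train_blocks$label_um
  y_mu <- mean(y)
  y_sd <- sd(y)
  if (!is.finite(y_sd) || y_sd == 0) y_sd <- 1
  obj$label_stats <- c(mean = y_mu, sd = y_sd)
  yz <- (y - y_mu) / y_sd
  yz_val <- (val_blocks$label_um - y_mu) / y_sd

  if (config$model %in% c("LSTM", "GRU")) {
    obj$fit <- fit_recurrent(config, train_blocks, val_blocks, yz, yz_val,
                             stats, aoi)
  } else {
    Xtr <- flatten_for_tabular(build_feature_tensor(train_blocks, stats, aoi))
    Xval <- flatten_for_tabular(build_feature_tensor(val_blocks, stats, aoi))
    obj$fit <- switch(
      config$model,
      LINEAR = fit_linear_pinv(Xtr, yz),
      RIDGE = fit_glmnet(Xtr, yz, Xval, yz_val, alpha = 0, config),
      LASSO = fit_glmnet(Xtr, yz, Xval, yz_val, alpha = 1, config),
      RF = fit_rf(Xtr, yz, config),
      GBM = fit_gbm(Xtr, yz, Xval, yz_val, config)
    )
  }
  class(obj) <- "pupil_model"
  obj
}

# unregularized least squares through an SVD pseudo-inverse; the flattened
# feature matrix is typically rank deficient (p >> n) and a plain solve
# would blow up
fit_linear_pinv <- function(X, y, tol = 1e-10) {
  Xc <- cbind(1, X)
  sv <- svd(Xc)
  keep <- sv$d > tol * sv$d[1]
  coef <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
  list(kind = "linear", coef = drop(coef))
}

fit_glmnet <- function(X, y, Xval, yval, alpha, config) {
  if (sd(y) == 0) {
    # constant target: glmnet cannot standardize; the optimum is the constant
    return(list(kind = "const", value = y[1]))
  }
  # penalty path down to near-OLS; the validation split picks the penalty
  lambda_max <- max(abs(crossprod(X, y - mean(y)))) / nrow(X)
  lambda_max <- max(lambda_max, 1e-4)
  lambda <- lambda_max * 10^seq(0.5, -8, length.out = 80)
  fit <- glmnet::glmnet(X, y, alpha = alpha, lambda = lambda,
                        standardize = TRUE)
  pv <- predict(fit, newx = Xval)
  mse <- colMeans((pv - yval)^2)
  best <- fit$lambda[which.min(mse)]
  list(kind = "glmnet", fit = fit, lambda = best,
       val_mse = min(mse))
}

fit_rf <- function(X, y, config) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(df)))
  df$.y <- y
  num_trees <- config$extra$num_trees %||% 500L
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = num_trees, seed = config$seed, num.threads = 1
  )
  list(kind = "rf", fit = fit, cols = ncol(X))
}

fit_gbm <- function(X, y, Xval, yval, config) {
  nrounds <- config$extra$nrounds %||% 200L
  dtr <- xgboost::xgb.DMatrix(X, label = y)
  dval <- xgboost::xgb.DMatrix(Xval, label = yval)
  fit <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = 0.1, max_depth = 3,
                  nthread = 1, seed = config$seed),
    data = dtr, nrounds = nrounds,
    evals = list(val = dval),
    early_stopping_rounds = 20, verbose = 0
  )
  list(kind = "gbm", fit = fit)
}

#' Predict pupil diameters for a set of blocks
#'
#' @param object A trained [train_model()] object.
#' @param newdata A `pupil_blocks` tibble, featurized with the model's own
#'   training statistics.
#' @param ... Unused.
#' @return A numeric vector of predictions in micrometres (finite and
#'   positive).
#' @export
predict.pupil_model <- function(object, newdata, ...) {
  cfg <- object$config
  if (cfg$model == "INPUT_MEAN") {
    return(input_mean_predict(newdata))
  }
  if (cfg$model %in% c("LSTM", "GRU")) {
    pz <- predict_recurrent(object, newdata)
  } else {
    X <- flatten_for_tabular(build_feature_tensor(newdata, object$stats, object$aoi))
    pz <- switch(
      object$fit$kind,
      const = rep(object$fit$value, nrow(X)),
      linear = drop(cbind(1, X) %*% object$fit$coef),
      glmnet = drop(predict(object$fit$fit, newx = X, s = object$fit$lambda)),
      rf = {
        df <- as.data.frame(X)
        names(df) <- paste0("f", seq_len(ncol(df)))
        predict(object$fit$fit, data = df, num.threads = 1)$predictions
      },
      gbm = predict(object$fit$fit, newdata = xgboost::xgb.DMatrix(X))
    )
  }
  pred <- pz * object$label_stats[["sd"]] + object$label_stats[["mean"]]
  if (any(!is.finite(pred))) stop_pf("non-finite predictions produced")
  pmax(pred, .Machine$double.eps)
}

#' @rdname predict.pupil_model
#' @param model A trained `pupil_model`.
#' @param blocks Blocks to predict.
#' @export
predict_batch <- function(model, blocks) predict(model, blocks)
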