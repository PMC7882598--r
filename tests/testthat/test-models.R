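test_that("analytic recurrent gradients match finite differences", {
  set.seed(7)
  Fn <- 3; T_ <- 6; N <- 5; H <- 4
  for (cell in c("lstm", "gru")) {
    opts <- list(cell = cell, hidden = H, embedding_dim = 3, vocab = 5,
                 use_embed = TRUE, seed = 11)
    X <- array(rnorm(Fn * T_ * N), dim = c(Fn, T_, N))
    A <- matrix(sample(1:4, T_ * N, TRUE), T_, N)
    len <- as.integer(c(6, 4, 2, 5, 3))
    for (n in seq_len(N)) if (len[n] < T_) A[(len[n] + 1):T_, n] <- 0L
    y <- rnorm(N)
    w <- pupilflow:::rnn_init_cpp(Fn, opts)
    lg <- pupilflow:::rnn_loss_grad_cpp(w, X, A, len, y, opts)
    eps <- 1e-6
    worst <- 0
    for (k in seq_along(w)) {
      idx <- sample(length(w[[k]]), min(length(w[[k]]), 12))
      for (i in idx) {
        wp <- w; wp[[k]][i] <- wp[[k]][i] + eps
        wm <- w; wm[[k]][i] <- wm[[k]][i] - eps
        gn <- (pupilflow:::rnn_loss_grad_cpp(wp, X, A, len, y, opts)$loss -
               pupilflow:::rnn_loss_grad_cpp(wm, X, A, len, y, opts)$loss) / (2 * eps)
        worst <- max(worst, abs(gn - lg$grads[[k]][i]))
      }
    }
    expect_lt(worst, 1e-7)
  }
})

test_that("input-mean predictions are exact hand means and padding-invariant", {
  one <- make_events(fix = tibble::tibble(
    start = c(1000, 11000), end = c(1300, 11300), x = 1, y = 1,
    p = c(2000, 2100)
  ))
  b1 <- segment_blocks(one, duration_ms = 15000)
  expect_equal(input_mean_predict(b1), 2000)

  two <- make_events(fix = tibble::tibble(
    start = c(1000, 5000, 11000), end = c(1300, 5300, 11300), x = 1, y = 1,
    p = c(2000, 2200, 2500)
  ))
  b2 <- segment_blocks(two, duration_ms = 15000)
  expect_equal(input_mean_predict(b2), 2100)

  cfg <- model_config("INPUT_MEAN")
  m <- train_model(cfg, b2, b2, feature_set(diameter = TRUE))
  expect_equal(predict(m, b2), input_mean_predict(b2))
})

test_that("all models recover a constant label to within 1%", {
  blocks <- tiny_blocks()[1:80, ]
  blocks$label_um <- 2000
  fs <- feature_set(diameter = TRUE)
  tr <- blocks[1:60, ]; va <- blocks[61:80, ]
  for (mt in c("LINEAR", "RIDGE", "LASSO", "RF", "GBM")) {
    m <- train_model(model_config(mt, seed = 2), tr, va, fs)
    p <- predict(m, va)
    expect_lt(max(abs(p - 2000)) / 2000, 0.01, label = mt)
  }
  m <- train_model(model_config("LSTM", profile = "fast", epochs = 30,
                                early_stopping_patience = 30, seed = 2),
                   tr, va, fs)
  expect_lt(max(abs(predict(m, va) - 2000)) / 2000, 0.01)
})

test_that("ridge recovers a noiseless affine map of the input mean to < 1 um", {
  blocks <- regular_affine_blocks()
  fs <- feature_set(diameter = TRUE)
  tr <- blocks[1:400, ]; va <- blocks[401:500, ]; te <- blocks[501:600, ]
  m <- train_model(model_config("RIDGE", seed = 3), tr, va, fs)
  expect_lt(rmse(predict(m, te), te$label_um), 1)
  # closed-form least-squares oracle on the same flattened features
  stats <- fit_feature_stats(tr, fs)
  Xtr <- cbind(1, flatten_for_tabular(build_feature_tensor(tr, stats)))
  Xte <- cbind(1, flatten_for_tabular(build_feature_tensor(te, stats)))
  sv <- svd(Xtr)
  keep <- sv$d > 1e-8 * sv$d[1]
  beta <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% tr$label_um) / sv$d[keep])
  expect_lt(rmse(drop(Xte %*% beta), te$label_um), 1)
})

test_that("recurrent training improves over epochs and early-stops on the best model", {
  blocks <- tiny_blocks()[1:100, ]
  fs <- feature_set(diameter = TRUE, aoi = TRUE)
  st <- tiny_study()
  m <- train_model(model_config("LSTM", profile = "fast", epochs = 40,
                                early_stopping_patience = 40, seed = 4),
                   blocks[1:70, ], blocks[71:100, ], fs, aoi = st$aoi)
  h <- m$fit$history
  expect_equal(nrow(h), 40)
  expect_lt(h$train_loss[40], h$train_loss[1])
  # the retained checkpoint minimizes the validation loss seen so far
  expect_equal(m$fit$best_epoch, which.min(h$val_loss))
  expect_equal(m$fit$best_val_loss, min(h$val_loss))
  expect_true(all(is.finite(predict(m, blocks))))
})

test_that("the GRU variant trains with the same interface and no dropout", {
  blocks <- tiny_blocks()[1:60, ]
  fs <- feature_set(diameter = TRUE)
  cfg <- model_config("GRU", profile = "fast", epochs = 15,
                      early_stopping_patience = 15, seed = 5)
  expect_equal(cfg$recurrent_dropout, 0)
  m <- train_model(cfg, blocks[1:45, ], blocks[46:60, ], fs)
  p <- predict(m, blocks)
  expect_length(p, 60)
  expect_true(all(is.finite(p) & p > 0))
})

test_that("predictions are stable under block reordering", {
  blocks <- tiny_blocks()[1:50, ]
  fs <- feature_set(diameter = TRUE)
  m <- train_model(model_config("RIDGE", seed = 6), blocks[1:35, ],
                   blocks[36:50, ], fs)
  p <- predict(m, blocks)
  sh <- pupilflow:::with_seed(8, sample.int(50))
  expect_equal(predict(m, blocks[sh, ]), p[sh])
})

test_that("fixed seeds reproduce classical models bitwise and recurrent models to 1e-4", {
  blocks <- tiny_blocks()[1:80, ]
  fs <- feature_set(diameter = TRUE)
  tr <- blocks[1:60, ]; va <- blocks[61:80, ]
  for (mt in c("RIDGE", "RF", "GBM")) {
    p1 <- predict(train_model(model_config(mt, seed = 11), tr, va, fs), va)
    p2 <- predict(train_model(model_config(mt, seed = 11), tr, va, fs), va)
    expect_identical(p1, p2, label = mt)
  }
  cfg <- model_config("LSTM", profile = "fast", epochs = 12,
                      early_stopping_patience = 12, seed = 11)
  q1 <- predict(train_model(cfg, tr, va, fs), va)
  q2 <- predict(train_model(cfg, tr, va, fs), va)
  expect_lt(max(abs(q1 - q2)), 1e-4)
})

test_that("with diameter inputs every model stays within 1.5x the input-mean RMSE", {
  blocks <- tiny_blocks()
  st <- tiny_study()
  fs <- feature_set(diameter = TRUE)
  spec_im <- experiment_spec(model_config("INPUT_MEAN"), fs, runs = 1, seed = 13)
  base <- experiment_rmse(blocks, spec_im)$mean_rmse
  for (mt in c("RIDGE", "LASSO", "RF", "GBM")) {
    spec <- experiment_spec(model_config(mt, seed = 13), fs, runs = 1, seed = 13)
    e <- experiment_rmse(blocks, spec)
    expect_lt(e$mean_rmse, 1.5 * base, label = mt)
  }
  spec_l <- experiment_spec(
    model_config("LSTM", profile = "fast", epochs = 40,
                 early_stopping_patience = 15, seed = 13),
    fs, runs = 1, seed = 13)
  expect_lt(experiment_rmse(blocks, spec_l)$mean_rmse, 1.5 * base)
})

test_that("AOI embeddings do not worsen the LSTM on the default benchmark", {
  # the scene script ties AOI occupancy to luminance, so the embedding
  # channel carries predictive information
  e_fd <- bench_lstm_experiment("bench_lstm_fix_diam",
                                feature_set(diameter = TRUE))
  e_full <- bench_lstm_experiment("bench_lstm_full",
                                  feature_set(diameter = TRUE, aoi = TRUE))
  expect_lt(e_full$mean_rmse, e_fd$mean_rmse * 1.05)
})

test_that("tidy and glance methods return the documented shapes", {
  blocks <- tiny_blocks()[1:60, ]
  fs <- feature_set(diameter = TRUE)
  m <- train_model(model_config("RIDGE", seed = 14), blocks[1:45, ],
                   blocks[46:60, ], fs)
  td <- generics::tidy(m)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- generics::glance(m)
  expect_equal(gl$model, "RIDGE")
  spec <- experiment_spec(model_config("INPUT_MEAN"), fs, runs = 2, seed = 14)
  e <- experiment_rmse(blocks, spec)
  expect_equal(nrow(generics::tidy(e)), 2)
  expect_equal(generics::glance(e)$mean_rmse, e$mean_rmse)
})
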