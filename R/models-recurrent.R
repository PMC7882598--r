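# R-side wrapper around the compiled bidirectional recurrent regressor.
#
# The recurrent models run over the per-fixation sequence: z-scored numeric
# fixation features, concatenated (when enabled) with a learned embedding of
# the fixation's AOI code, through two stacked bidirectional LSTM/GRU layers
# and a scalar regression head. Saccade/blink information enters as
# per-fixation covariates inside the fixation channel (see
# block_channel_matrices), keeping one sequence axis per block.

rnn_opts <- function(config, use_embed) {
  list(
    cell = tolower(config$model),
    hidden = config$hidden_units,
    embedding_dim = config$embedding_dim,
    vocab = length(.EMB_VOCAB),
    use_embed = use_embed,
    epochs = config$epochs,
    patience = config$early_stopping_patience,
    batch_size = config$batch_size,
    learning_rate = config$learning_rate,
    recurrent_dropout = config$recurrent_dropout,
    seed = config$seed
  )
}

tensor_for_rnn <- function(blocks, stats, aoi) {
  tensor <- build_feature_tensor(blocks, stats, aoi)
  n <- dim(tensor$fix)[3]
  A <- if (!is.null(tensor$aoi)) {
    matrix(as.integer(tensor$aoi - 1L), nrow(tensor$aoi), n)  # 0-based for C++
  } else {
    matrix(0L, dim(tensor$fix)[2], n)
  }
  list(X = tensor$fix, A = A, len = as.integer(tensor$fix_len))
}

fit_recurrent <- function(config, train_blocks, val_blocks, yz, yz_val,
                          stats, aoi) {
  use_embed <- isTRUE(stats$featureset$aoi)
  tr <- tensor_for_rnn(train_blocks, stats, aoi)
  va <- tensor_for_rnn(val_blocks, stats, aoi)
  opts <- rnn_opts(config, use_embed)
  res <- rnn_train_cpp(tr$X, tr$A, tr$len, yz, va$X, va$A, va$len, yz_val, opts)
  list(kind = "rnn", weights = res$weights,
       history = tibble::tibble(
         epoch = seq_along(res$train_loss),
         train_loss = res$train_loss,
         val_loss = res$val_loss
       ),
       best_epoch = res$best_epoch, best_val_loss = res$best_val_loss,
       opts = opts)
}

predict_recurrent <- function(object, blocks) {
  te <- tensor_for_rnn(blocks, object$stats, object$aoi)
  drop(rnn_predict_cpp(object$fit$weights, te$X, te$A, te$len, object$fit$opts))
}
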