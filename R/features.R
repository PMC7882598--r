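#' Define an input feature set
#'
#' The studied feature combinations always include fixation features
#' (positions, durations, start times, and their first-order differences)
#' and optionally add the per-fixation pupil diameter, saccade/blink
#' channels, and learned AOI embeddings.
#'
#' @param diameter Include the per-fixation pupil diameter (and its
#'   difference) in the fixation channel.
#' @param saccades_blinks Include the saccade and blink channels (and
#'   saccade/blink-derived per-fixation covariates for the recurrent
#'   models).
#' @param aoi Include the AOI channel (embedded by recurrent models,
#'   one-hot encoded for tabular ones).
#' @return An object of class `pupil_feature_set`.
#' @examples
#' feature_set()                       # FIX only
#' feature_set(diameter = TRUE)        # FIX + DIAM
#' feature_set(TRUE, TRUE, TRUE)       # full menu + AOI
#' @export
feature_set <- function(diameter = FALSE, saccades_blinks = FALSE, aoi = FALSE) {
  structure(
    list(fix = TRUE, diameter = diameter,
         saccades_blinks = saccades_blinks, aoi = aoi),
    class = "pupil_feature_set"
  )
}

#' @export
format.pupil_feature_set <- function(x, ...) {
  parts <- c("FIX",
             if (x$diameter) "DIAM",
             if (x$saccades_blinks) "SACC+BLINK",
             if (x$aoi) "AOI")
  paste(parts, collapse = "+")
}

#' @export
print.pupil_feature_set <- function(x, ...) {
  cat("<pupil_feature_set> ", format(x), "\n", sep = "")
  invisible(x)
}

# first-order difference with 0 at the first element
diff0 <- function(v) if (length(v) == 0) numeric(0) else c(0, diff(v))

# append per-column first differences, robust to 0- and 1-row inputs
with_diffs <- function(m) {
  d <- apply(m, 2, diff0)
  if (!is.matrix(d)) {
    d <- matrix(d, nrow = nrow(m), dimnames = list(NULL, colnames(m)))
  }
  colnames(d) <- paste0("d_", colnames(m))
  cbind(m, d)
}

fix_feature_names <- function(featureset) {
  base <- c("x", "y", "dur", "start")
  if (featureset$diameter) base <- c(base, "diam")
  nm <- c(base, paste0("d_", base))
  if (featureset$saccades_blinks) {
    nm <- c(nm, "prev_sacc_dur", "prev_sacc_dx", "prev_sacc_dy",
            "since_blink", "blinks_gap")
  }
  nm
}

sacc_feature_names <- function() {
  base <- c("sx", "sy", "ex", "ey", "dur", "start")
  c(base, paste0("d_", base))
}

blink_feature_names <- function() c("start", "dur", "d_start", "d_dur")

# Raw (pre-normalization) per-event feature matrices for one block.
# Times are relative to the input-window start so features are comparable
# across blocks. Returns list(fix=, sacc=, blink=) of matrices
# [n_events x n_features]; sacc/blink NULL unless enabled.
block_channel_matrices <- function(block_row, featureset) {
  fx <- block_row$input_fix[[1]]
  t0 <- block_row$t0_ms
  start <- fx$start_ms - t0
  base <- cbind(x = fx$x_px, y = fx$y_px, dur = fx$duration_ms, start = start)
  if (featureset$diameter) base <- cbind(base, diam = fx$pupil_um)
  m <- with_diffs(base)
  sc <- NULL
  bl <- NULL
  if (featureset$saccades_blinks) {
    sac <- block_row$input_sacc[[1]]
    bli <- block_row$input_blink[[1]]
    # per-fixation covariates: properties of the most recent preceding
    # saccade and blink activity in the gap since the previous fixation
    prev_dur <- numeric(nrow(fx)); prev_dx <- numeric(nrow(fx))
    prev_dy <- numeric(nrow(fx)); since_blink <- numeric(nrow(fx))
    blinks_gap <- numeric(nrow(fx))
    win_ms <- block_row$input_end_ms - t0
    for (i in seq_len(nrow(fx))) {
      before <- sac[sac$start_ms <= fx$start_ms[i], , drop = FALSE]
      if (nrow(before) > 0) {
        j <- which.max(before$start_ms)
        prev_dur[i] <- before$duration_ms[j]
        prev_dx[i] <- before$end_x_px[j] - before$x_px[j]
        prev_dy[i] <- before$end_y_px[j] - before$y_px[j]
        if (!is.finite(prev_dx[i])) prev_dx[i] <- 0
        if (!is.finite(prev_dy[i])) prev_dy[i] <- 0
      }
      bb <- bli[bli$start_ms <= fx$start_ms[i], , drop = FALSE]
      since_blink[i] <- if (nrow(bb) > 0) fx$start_ms[i] - max(bb$end_ms) else win_ms
      gap_start <- if (i == 1) t0 else fx$end_ms[i - 1]
      blinks_gap[i] <- sum(bli$start_ms >= gap_start & bli$start_ms <= fx$start_ms[i])
    }
    m <- cbind(m, prev_sacc_dur = prev_dur, prev_sacc_dx = prev_dx,
               prev_sacc_dy = prev_dy, since_blink = pmax(since_blink, 0),
               blinks_gap = blinks_gap)
    if (nrow(sac) > 0) {
      sbase <- cbind(sx = sac$x_px, sy = sac$y_px,
                     ex = sac$end_x_px, ey = sac$end_y_px,
                     dur = sac$duration_ms, start = sac$start_ms - t0)
      sbase[!is.finite(sbase)] <- 0
      sc <- with_diffs(sbase)
    } else {
      sc <- matrix(0, 0, 12, dimnames = list(NULL, sacc_feature_names()))
    }
    if (nrow(bli) > 0) {
      bbase <- cbind(start = bli$start_ms - t0, dur = bli$duration_ms)
      bl <- with_diffs(bbase)
    } else {
      bl <- matrix(0, 0, 4, dimnames = list(NULL, blink_feature_names()))
    }
    colnames(sc) <- sacc_feature_names()
    colnames(bl) <- blink_feature_names()
  }
  colnames(m) <- fix_feature_names(featureset)
  list(fix = m, sacc = sc, blink = bl)
}

#' Fit per-feature normalization statistics on training blocks
#'
#' Computes the per-feature mean and population standard deviation over all
#' valid (unpadded) event rows of the training blocks, for each enabled
#' channel, together with the per-channel maximum sequence lengths used for
#' padding. Features with zero spread get their SD guarded to 1 so z-scores
#' stay finite. Statistics must be fitted on the training split only; they
#' are reused unchanged for validation and test blocks.
#'
#' @param blocks Training blocks (a `pupil_blocks` tibble with at least 2
#'   rows).
#' @param featureset A [feature_set()].
#' @return An object of class `pupil_feature_stats` with elements `fix`,
#'   `sacc`, `blink` (each a list with `mean`, `sd`) and `max_lengths`.
#' @export
fit_feature_stats <- function(blocks, featureset) {
  if (nrow(blocks) == 0) stop_pf("cannot fit feature statistics on an empty training set")
  if (nrow(blocks) < 2) stop_pf("need at least 2 training blocks to fit feature statistics")
  mats <- purrr::map(seq_len(nrow(blocks)),
                     function(i) block_channel_matrices(blocks[i, ], featureset))
  chan_stats <- function(key) {
    ms <- purrr::map(mats, key)
    if (is.null(ms[[1]])) return(NULL)
    all <- do.call(rbind, ms)
    if (nrow(all) == 0) {
      mu <- setNames(rep(0, ncol(all)), colnames(all))
      sdv <- setNames(rep(1, ncol(all)), colnames(all))
      return(list(mean = mu, sd = sdv, max_len = 0L))
    }
    mu <- colMeans(all)
    sdv <- sqrt(colMeans(sweep(all, 2, mu)^2))  # population SD
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    list(mean = mu, sd = sdv,
         max_len = max(vapply(ms, nrow, integer(1))))
  }
  out <- list(
    fix = chan_stats("fix"),
    sacc = chan_stats("sacc"),
    blink = chan_stats("blink"),
    featureset = featureset
  )
  out$max_lengths <- list(
    fix = out$fix$max_len,
    sacc = if (!is.null(out$sacc)) out$sacc$max_len else 0L,
    blink = if (!is.null(out$blink)) out$blink$max_len else 0L
  )
  structure(out, class = "pupil_feature_stats")
}

# embedding vocabulary indices (1-based rows of the embedding matrix):
# PAD = 1, NONE = 2, INSTRUCTOR = 3, TEXT = 4, IMAGE = 5
.EMB_VOCAB <- c(PAD = 1L, NONE = 2L, INSTRUCTOR = 3L, TEXT = 4L, IMAGE = 5L)

#' Build padded, normalized feature tensors for a set of blocks
#'
#' Numeric features are z-scored with training statistics; sequences are
#' padded to the training-split maximum lengths with the per-feature
#' training mean, which is 0 after normalization. The AOI channel (present
#' only when the feature set enables it) carries integer codes per fixation
#' with a dedicated padding code. Blocks longer than the training maxima are
#' truncated from the end of the window with a warning.
#'
#' @param blocks A `pupil_blocks` tibble.
#' @param stats A fitted [fit_feature_stats()] object.
#' @param aoi An AOI tibble; required when the feature set includes AOI.
#' @return An object of class `pupil_feature_tensor`: arrays `fix`
#'   (`features x max_fix x n_blocks`), optional `sacc`, `blink`, an integer
#'   `aoi` matrix (`max_fix x n_blocks`, embedding indices with PAD = 1),
#'   valid lengths per channel, and feature names.
#' @export
build_feature_tensor <- function(blocks, stats, aoi = NULL) {
  featureset <- stats$featureset
  if (featureset$aoi && is.null(aoi)) stop_pf("AOI features requested but no AOI table given")
  n <- nrow(blocks)
  if (n == 0) stop_pf("cannot build a tensor from zero blocks")
  ml <- stats$max_lengths
  n_trunc <- 0L

  pack_channel <- function(key, max_len) {
    st <- stats[[key]]
    f <- length(st$mean)
    arr <- array(0, dim = c(f, max_len, n),
                 dimnames = list(names(st$mean), NULL, NULL))
    lens <- integer(n)
    for (i in seq_len(n)) {
      m <- block_channel_matrices(blocks[i, ], featureset)[[key]]
      if (nrow(m) > max_len) {
        n_trunc <<- n_trunc + 1L
        m <- m[seq_len(max_len), , drop = FALSE]
      }
      lens[i] <- nrow(m)
      if (nrow(m) > 0) {
        z <- sweep(sweep(m, 2, st$mean), 2, st$sd, "/")
        arr[, seq_len(nrow(m)), i] <- t(z)
      }
    }
    list(arr = arr, len = lens)
  }

  fixc <- pack_channel("fix", ml$fix)
  out <- list(
    fix = fixc$arr, fix_len = fixc$len,
    featureset = featureset,
    feature_names = fix_feature_names(featureset),
    max_lengths = ml
  )
  if (featureset$saccades_blinks) {
    sc <- pack_channel("sacc", max(ml$sacc, 1L))
    bl <- pack_channel("blink", max(ml$blink, 1L))
    out$sacc <- sc$arr; out$sacc_len <- sc$len
    out$blink <- bl$arr; out$blink_len <- bl$len
  }
  if (featureset$aoi) {
    am <- matrix(.EMB_VOCAB[["PAD"]], nrow = ml$fix, ncol = n)
    for (i in seq_len(n)) {
      fx <- blocks$input_fix[[i]]
      k <- min(nrow(fx), ml$fix)
      aoi_one <- aoi[aoi$video_id == blocks$video_id[i] &
                       aoi$modality == blocks$modality[i], , drop = FALSE]
      codes <- map_fixation_to_aoi(fx$x_px[seq_len(k)], fx$y_px[seq_len(k)], aoi_one)
      am[seq_len(k), i] <- .EMB_VOCAB[codes]
    }
    out$aoi <- am
  }
  if (n_trunc > 0) {
    warn_pf("%d block(s) exceeded the training maximum length and were truncated", n_trunc)
  }
  structure(out, class = "pupil_feature_tensor")
}

#' Flatten feature tensors into fixed-length vectors for tabular models
#'
#' Channels are concatenated row-major (all features of event 1, then event
#' 2, ...) into one constant-length vector per block, so linear and tree
#' models can consume the padded sequences. When the AOI channel is present
#' its codes are one-hot encoded over the four observable classes (`NONE`,
#' `INSTRUCTOR`, `TEXT`, `IMAGE`); padded positions encode as all-zero.
#'
#' @param tensor A [build_feature_tensor()] result.
#' @return A numeric matrix, one row per block.
#' @export
flatten_for_tabular <- function(tensor) {
  n <- dim(tensor$fix)[3]
  flat_arr <- function(arr) {
    t(vapply(seq_len(dim(arr)[3]), function(i) as.vector(arr[, , i, drop = FALSE]),
             numeric(dim(arr)[1] * dim(arr)[2])))
  }
  out <- flat_arr(tensor$fix)
  if (!is.null(tensor$aoi)) {
    codes <- setdiff(names(.EMB_VOCAB), "PAD")
    oh <- matrix(0, n, length(codes) * nrow(tensor$aoi))
    for (i in seq_len(n)) {
      a <- tensor$aoi[, i]
      for (ci in seq_along(codes)) {
        oh[i, (seq_len(nrow(tensor$aoi)) - 1) * length(codes) + ci] <-
          as.numeric(a == .EMB_VOCAB[[codes[ci]]])
      }
    }
    out <- cbind(out, oh)
  }
  if (!is.null(tensor$sacc)) out <- cbind(out, flat_arr(tensor$sacc))
  if (!is.null(tensor$blink)) out <- cbind(out, flat_arr(tensor$blink))
  out
}
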