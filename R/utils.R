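#' Derive a child seed from a master seed
#'
#' One master seed fans out deterministically to per-run, per-model and
#' per-stream seeds. The mixing is a small multiplicative-congruential hash
#' kept inside the 32-bit signed integer range.
#'
#' @param master Integer master seed.
#' @param ... Further integer keys (run index, stream index, ...).
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
fanout_seed <- function(master, ...) {
  keys <- c(master, ...)
  s <- 0
  for (k in keys) {
    s <- (s * 69069 + (as.numeric(k) %% 2147483647) + 1) %% 2147483647
  }
  as.integer(s + 1)
}

# Evaluate `expr` under a given RNG seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stop_pf <- function(...) stop(sprintf(...), call. = FALSE)

warn_pf <- function(...) warning(sprintf(...), call. = FALSE)

assert_cols <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_pf("%s is missing required column(s): %s", what,
            paste(missing, collapse = ", "))
  }
}
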