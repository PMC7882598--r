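#' Root-mean-square error
#'
#' @param predictions,truths Equal-length numeric vectors (micrometres).
#' @return `sqrt(mean((predictions - truths)^2))`.
#' @export
rmse <- function(predictions, truths) {
  if (length(predictions) == 0 || length(predictions) != length(truths)) {
    stop_pf("rmse needs two equal-length, non-empty vectors")
  }
  sqrt(mean((predictions - truths)^2))
}

#' Mann-Whitney U test
#'
#' Computes `U = #\{(a, b): a > b\} + 0.5 #\{a == b\}` over all pairs and a
#' two-sided p-value: by full enumeration of the permutation distribution
#' when the pooled sample size is at most 20, otherwise by the normal
#' approximation with tie correction and continuity correction.
#'
#' @param sample_a,sample_b Non-empty numeric vectors.
#' @return A list with `U`, `p_value`, and `method`.
#' @export
mann_whitney_u <- function(sample_a, sample_b) {
  na <- length(sample_a); nb <- length(sample_b)
  if (na == 0 || nb == 0) stop_pf("both samples must be non-empty")
  u_stat <- function(a, b) {
    r <- rank(c(a, b))
    sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  }
  U <- u_stat(sample_a, sample_b)
  n <- na + nb
  mu <- na * nb / 2
  if (n <= 20) {
    pool <- c(sample_a, sample_b)
    combs <- utils::combn(n, na)
    us <- apply(combs, 2, function(idx) u_stat(pool[idx], pool[-idx]))
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-12)
    method <- "exact enumeration"
  } else {
    r <- rank(c(sample_a, sample_b))
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * ((n + 1) - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(U - mu) - 0.5) / sigma  # continuity correction
      p <- 2 * pnorm(-max(z, 0))
    }
    method <- "normal approximation with tie correction"
  }
  list(U = U, p_value = min(p, 1), method = method)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, with a two-sided p-value from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))`.
#'
#' @param x,y Equal-length numeric vectors of length at least 3.
#' @return A list with `rho`, `p_value`, and `n`.
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (n != length(y) || n < 3) stop_pf("spearman_rho needs equal lengths >= 3")
  if (sd(x) == 0 || sd(y) == 0) {
    stop_pf("spearman correlation undefined for constant input")
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tval), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Fisher Z comparison of two independent correlations
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, with a
#' two-sided p-value from the standard normal.
#'
#' @param r1,r2 Correlation coefficients with `|r| < 1`.
#' @param n1,n2 Sample sizes behind each correlation (must exceed 3).
#' @return A list with `z` and `p_value`.
#' @export
fisher_z_compare <- function(r1, r2, n1, n2) {
  if (n1 <= 3 || n2 <= 3) stop_pf("fisher_z_compare needs n > 3 in both samples")
  if (abs(r1) >= 1 || abs(r2) >= 1) stop_pf("correlations must satisfy |r| < 1")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Bottom and top performance tertiles
#'
#' Subjects are sorted by score (ties broken by subject id for
#' determinism); the bottom `floor(n/3)` and top `floor(n/3)` form the two
#' groups.
#'
#' @param scores A tibble with `subject_id` and `score`.
#' @return A list with character vectors `bottom` and `top`.
#' @export
tertile_groups <- function(scores) {
  n <- nrow(scores)
  if (n < 3) stop_pf("tertile grouping needs at least 3 subjects")
  o <- order(scores$score, scores$subject_id)
  k <- floor(n / 3)
  list(
    bottom = scores$subject_id[o][seq_len(k)],
    top = scores$subject_id[o][seq(n - k + 1, n)]
  )
}

#' Area under the ROC curve for two groups
#'
#' `AUC = (#\{(t, b): t > b\} + 0.5 #\{t == b\}) / (n_t n_b)`: the
#' probability that a randomly chosen member of the top group carries a
#' larger measure value than a randomly chosen member of the bottom group.
#' Identical to the full threshold-sweep construction of the ROC curve, and
#' to the Mann-Whitney `U / (n_t n_b)`.
#'
#' @param scores_top,scores_bottom Measure values in the two groups.
#' @return The AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores_top, scores_bottom) {
  nt <- length(scores_top); nb <- length(scores_bottom)
  if (nt == 0 || nb == 0) stop_pf("both groups must be non-empty")
  r <- rank(c(scores_top, scores_bottom))
  U <- sum(r[seq_len(nt)]) - nt * (nt + 1) / 2
  U / (nt * nb)
}

#' Permutation test for a group-separation AUC
#'
#' Shuffles the group labels `n_perm` times and reports
#' `p = (1 + #\{AUC_perm >= AUC_obs\}) / (n_perm + 1)` (the add-one
#' estimator, which cannot return 0). Reproducible for a fixed seed; the
#' caller's RNG state is left untouched.
#'
#' @param values Measure values, one per subject.
#' @param is_top Logical vector: `TRUE` for top-group members.
#' @param n_perm Number of label permutations (default 10000).
#' @param seed Integer seed.
#' @return An object of class `pupil_permutation`: `auc`, `p_value`,
#'   `n_perm`, and the permuted-AUC null sample `null_auc`.
#' @export
permutation_auc_pvalue <- function(values, is_top, n_perm = 10000, seed = 1L) {
  if (length(values) != length(is_top)) stop_pf("values and is_top must align")
  if (sum(is_top) == 0 || sum(!is_top) == 0) {
    stop_pf("both groups must be non-empty")
  }
  if (n_perm < 100) warn_pf("n_perm = %d is small; p-value will be coarse", n_perm)
  obs <- roc_auc(values[is_top], values[!is_top])
  null_auc <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sh <- sample(is_top)
      roc_auc(values[sh], values[!sh])
    }, numeric(1))
  })
  structure(
    list(auc = obs,
         p_value = (1 + sum(null_auc >= obs - 1e-12)) / (n_perm + 1),
         n_perm = n_perm, null_auc = null_auc,
         n_top = sum(is_top), n_bottom = sum(!is_top)),
    class = "pupil_permutation"
  )
}

#' @export
print.pupil_permutation <- function(x, ...) {
  cat(sprintf("<pupil_permutation> AUC = %.3f, p = %.4g (%d permutations, %d vs %d)\n",
              x$auc, x$p_value, x$n_perm, x$n_top, x$n_bottom))
  invisible(x)
}
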