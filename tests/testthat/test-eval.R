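# brute-force reference implementations (independent oracles)
bf_u <- function(a, b) {
  u <- 0
  for (x in a) for (y in b) u <- u + (x > y) + 0.5 * (x == y)
  u
}
bf_auc <- function(top, bottom) bf_u(top, bottom) / (length(top) * length(bottom))
bf_rmse <- function(p, t) sqrt(sum((p - t)^2) / length(p))
bf_spearman <- function(x, y) stats::cor(rank(x), rank(y))

test_that("rmse matches hand evaluation and the brute-force oracle", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(10, 100), c(10, 40)), sqrt(1800))  # residuals (0, 60)
  expect_equal(rmse(rep(5, 4), rep(2, 4)), 3)            # all residuals equal
  set.seed(31)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    p <- rnorm(n); t <- rnorm(n)
    expect_equal(rmse(p, t), bf_rmse(p, t), tolerance = 1e-9)
  }
  expect_error(rmse(numeric(), numeric()), "non-empty")
})

test_that("Mann-Whitney U matches brute-force pair counting with the tie rule", {
  expect_equal(mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$U, 0)
  expect_equal(mann_whitney_u(c(1, 2), c(1, 2))$U, 2)   # two half-ties + one win
  expect_equal(mann_whitney_u(5, 5)$p_value, 1)
  set.seed(32)
  for (i in 1:200) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    a <- sample(1:5, na, replace = TRUE)  # integer values force ties
    b <- sample(1:5, nb, replace = TRUE)
    expect_equal(mann_whitney_u(a, b)$U, bf_u(a, b), tolerance = 1e-9)
  }
})

test_that("Mann-Whitney p-values agree with an independent permutation oracle", {
  set.seed(33)
  for (i in 1:20) {
    na <- sample(3:5, 1); nb <- sample(3:5, 1)
    a <- rnorm(na); b <- rnorm(nb)
    res <- mann_whitney_u(a, b)
    # oracle: enumerate group assignments directly
    pool <- c(a, b); n <- na + nb; mu <- na * nb / 2
    us <- apply(utils::combn(n, na), 2,
                function(idx) bf_u(pool[idx], pool[-idx]))
    p_oracle <- mean(abs(us - mu) >= abs(bf_u(a, b) - mu) - 1e-12)
    expect_equal(res$p_value, p_oracle, tolerance = 1e-9)
  }
  # large-sample regime: cross-check against the standard implementation
  set.seed(34)
  a <- rnorm(30); b <- rnorm(25) + 0.5
  res <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res$U, unname(ref$statistic))
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("Spearman correlation matches hand values and cor.test", {
  expect_equal(spearman_rho(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_rho(1:5, -(1:5))$rho, -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(1, 3, 2))$rho, 0.5)
  set.seed(35)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- rnorm(n)
    if (sd(x) == 0) next
    expect_equal(spearman_rho(x, y)$rho, bf_spearman(x, y), tolerance = 1e-9)
  }
  x <- rnorm(20); y <- x + rnorm(20)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  res <- spearman_rho(x, y)
  expect_equal(res$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_rho(rep(1, 5), rnorm(5)), "constant")
})

test_that("Fisher Z comparison matches the closed form and is antisymmetric", {
  expect_equal(fisher_z_compare(0.4, 0.4, 50, 60)$z, 0)
  expect_equal(fisher_z_compare(0.4, 0.4, 50, 60)$p_value, 1)
  z <- fisher_z_compare(0.5, 0, 103, 103)$z
  expect_equal(z, atanh(0.5) / sqrt(2 / 100), tolerance = 1e-9)
  expect_equal(round(z, 3), 3.884)
  set.seed(36)
  for (i in 1:50) {
    r1 <- runif(1, -0.9, 0.9); r2 <- runif(1, -0.9, 0.9)
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    expect_equal(fisher_z_compare(r1, r2, n1, n2)$z,
                 -fisher_z_compare(r2, r1, n2, n1)$z, tolerance = 1e-12)
  }
  expect_error(fisher_z_compare(0.2, 0.1, 3, 10), "n > 3")
})

test_that("tertile grouping sizes and tie-breaking are deterministic", {
  sc39 <- tibble::tibble(subject_id = sprintf("s%02d", 1:39),
                         score = seq(0, 1, length.out = 39))
  tg <- tertile_groups(sc39)
  expect_length(tg$bottom, 13)
  expect_length(tg$top, 13)
  expect_true(max(sc39$score[sc39$subject_id %in% tg$bottom]) <
                min(sc39$score[sc39$subject_id %in% tg$top]))

  sc3 <- tibble::tibble(subject_id = c("a", "b", "c"), score = c(0.2, 0.5, 0.9))
  tg3 <- tertile_groups(sc3)
  expect_equal(tg3$bottom, "a")
  expect_equal(tg3$top, "c")

  tied <- tibble::tibble(subject_id = c("d", "b", "a", "c"), score = 0.5)
  tgt <- tertile_groups(tied)
  expect_equal(tgt$bottom, "a")  # id order breaks ties
  expect_equal(tgt$top, "d")
})

test_that("ROC AUC matches brute force and equals U / (n_t n_b) everywhere", {
  expect_equal(roc_auc(c(5, 6), c(1, 2)), 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_equal(roc_auc(c(3, 1), c(2, 0)), 0.75)
  set.seed(37)
  for (i in 1:200) {
    nt <- sample(2:8, 1); nb <- sample(2:8, 1)
    top <- sample(1:6, nt, replace = TRUE)
    bottom <- sample(1:6, nb, replace = TRUE)
    auc <- roc_auc(top, bottom)
    expect_equal(auc, bf_auc(top, bottom), tolerance = 1e-9)
    expect_equal(auc, mann_whitney_u(top, bottom)$U / (nt * nb),
                 tolerance = 1e-9)
  }
})

test_that("the permutation AUC test is calibrated, bounded, and seeded", {
  set.seed(38)
  v <- rnorm(20)
  is_top <- rep(c(TRUE, FALSE), each = 10)
  # perfectly separated groups: observed AUC is the maximum over permutations
  sep <- c(rnorm(10) + 100, rnorm(10))
  res <- permutation_auc_pvalue(sep, is_top, n_perm = 500, seed = 3)
  expect_equal(res$auc, 1)
  expect_gte(res$p_value, 1 / 501)
  expect_lt(res$p_value, 0.05)

  # exchangeable values: null AUC mean near 0.5
  res2 <- permutation_auc_pvalue(v, is_top, n_perm = 10000, seed = 4)
  expect_lt(abs(mean(res2$null_auc) - 0.5), 0.02)

  res3 <- permutation_auc_pvalue(v, is_top, n_perm = 1000, seed = 5)
  res4 <- permutation_auc_pvalue(v, is_top, n_perm = 1000, seed = 5)
  expect_identical(res3$p_value, res4$p_value)
  expect_warning(permutation_auc_pvalue(v, is_top, n_perm = 50, seed = 1),
                 "small")
})

test_that("experiment_rmse reduces correctly for single runs and oracle labels", {
  blocks <- tiny_blocks()[1:60, ]
  fs <- feature_set(diameter = TRUE)
  spec1 <- experiment_spec(model_config("INPUT_MEAN"), fs, runs = 1, seed = 5)
  e1 <- experiment_rmse(blocks, spec1)
  expect_equal(e1$sd_rmse, 0)
  expect_equal(e1$mean_rmse, e1$per_run_rmse$rmse[1])

  # oracle labels: set the label to the input mean, which INPUT_MEAN
  # predicts exactly -> RMSE 0 for any number of runs
  oracle_blocks <- blocks
  oracle_blocks$label_um <- oracle_blocks$input_mean_um
  spec3 <- experiment_spec(model_config("INPUT_MEAN"), fs, runs = 3, seed = 5)
  e3 <- experiment_rmse(oracle_blocks, spec3)
  expect_equal(e3$mean_rmse, 0)
  expect_equal(e3$sd_rmse, 0)
  expect_true(all(abs(e3$runs$residual_um) < 1e-12))
})

test_that("the repeated-split loop matches a brute-force reimplementation", {
  blocks <- tiny_blocks()[1:200, ]
  fs <- feature_set(diameter = TRUE)
  spec <- experiment_spec(model_config("INPUT_MEAN"), fs, runs = 10, seed = 77)
  e <- experiment_rmse(blocks, spec)
  # independent reimplementation of the whole loop for the input-mean model
  n <- nrow(blocks)
  rmses <- vapply(1:10, function(r) {
    idx <- pupilflow:::with_seed(fanout_seed(77, r), sample.int(n))
    n_tr <- floor(0.7 * n); n_val <- floor(0.1 * n)
    test <- blocks[idx[seq(n_tr + n_val + 1, n)], ]
    pred <- vapply(test$input_fix, function(fx) mean(fx$pupil_um), numeric(1))
    sqrt(mean((pred - test$label_um)^2))
  }, numeric(1))
  expect_equal(e$per_run_rmse$rmse, rmses, tolerance = 1e-9)
  expect_equal(e$mean_rmse, mean(rmses), tolerance = 1e-9)
  expect_equal(e$sd_rmse, sd(rmses), tolerance = 1e-9)
})

test_that("per-subject aggregates obey the residual identity", {
  expect_equal(
    residuals_by_subject(
      structure(list(runs = tibble::tibble(
        run = 1, subject_id = "s", truth_um = c(110, 86),
        prediction_um = c(100, 90),
        residual_um = c(10, -4)
      )), class = "pupil_experiment")
    )$mean_residual_um, 3
  )
  blocks <- tiny_blocks()[1:80, ]
  fs <- feature_set(diameter = TRUE)
  spec <- experiment_spec(model_config("INPUT_MEAN"), fs, runs = 2, seed = 6)
  e <- experiment_rmse(blocks, spec)
  expect_true(all(abs(e$runs$truth_um - e$runs$prediction_um -
                        e$runs$residual_um) < 1e-12))
  agg <- residuals_by_subject(e)
  expect_equal(agg$mean_truth_um,
               agg$mean_prediction_um + agg$mean_residual_um,
               tolerance = 1e-9)
  # permuting block order leaves aggregates unchanged
  e_perm <- e
  sh <- pupilflow:::with_seed(9, sample.int(nrow(e$runs)))
  e_perm$runs <- e$runs[sh, ]
  expect_equal(dplyr::arrange(residuals_by_subject(e_perm), subject_id),
               dplyr::arrange(agg, subject_id))
})

test_that("performance-group splitting assigns by threshold and flags degeneracy", {
  runs <- tibble::tibble(
    run = 1, subject_id = rep(c("s1", "s2"), each = 4),
    truth_um = rnorm(8, 2000, 10), prediction_um = rnorm(8, 2000, 10)
  )
  runs$residual_um <- runs$truth_um - runs$prediction_um
  e <- structure(list(runs = runs), class = "pupil_experiment")
  scores <- tibble::tibble(subject_id = c("s1", "s2"), score = c(0.40, 0.80))
  gc <- split_by_performance(e, scores, threshold = 0.59)
  expect_setequal(gc$group_summary$group, c("GreaterThanMean", "LesserThanMean"))
  expect_equal(gc$threshold, 0.59)

  # all subjects on one side: flagged, not an error
  expect_warning(split_by_performance(e, scores, threshold = 0.1), "one side")
})

test_that("the group U test holds its size under the null", {
  # equal error distributions in both groups: p > 0.05 in >= 9/10 replicates
  non_sig <- 0
  for (k in 1:10) {
    runs <- pupilflow:::with_seed(500 + k, {
      tibble::tibble(
        run = 1,
        subject_id = rep(sprintf("s%d", 1:10), each = 8),
        truth_um = rnorm(80, 2000, 50),
        prediction_um = rnorm(80, 2000, 50)
      )
    })
    runs$residual_um <- runs$truth_um - runs$prediction_um
    e <- structure(list(runs = runs), class = "pupil_experiment")
    scores <- tibble::tibble(subject_id = sprintf("s%d", 1:10),
                             score = rep(c(0.3, 0.9), 5))
    gc <- split_by_performance(e, scores, threshold = 0.59)
    non_sig <- non_sig + (gc$u_test$p_value > 0.05)
  }
  expect_gte(non_sig, 9)
})
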