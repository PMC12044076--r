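paired_xy <- function(n_subj, n_chan, effect = 0, seed = 1) {
  set.seed(seed)
  subj <- sprintf("s%02d", seq_len(n_subj))
  x <- rbind(matrix(rnorm(n_subj * n_chan, mean = effect), n_subj, n_chan),
             matrix(rnorm(n_subj * n_chan), n_subj, n_chan))
  list(x = x, y = factor(rep(c("caffeine", "placebo"), each = n_subj)),
       groups = rep(subj, 2))
}

test_that("grouped folds never split a subject across train and test", {
  d <- paired_xy(17, 2)
  folds <- grouped_kfold(d$groups, k = 10, seed = 3)
  expect_identical(length(unique(folds)), 10L)
  per_subj <- tapply(folds, d$groups, function(f) length(unique(f)))
  expect_true(all(per_subj == 1))
  expect_identical(folds, grouped_kfold(d$groups, k = 10, seed = 3))
  expect_error(grouped_kfold(d$groups, k = 20), "more folds than groups")
})

test_that("a perfectly separated feature decodes at 1.0 with minimal p", {
  d <- paired_xy(12, 2, effect = 20, seed = 2)
  res <- decode_single_feature(d$x, d$y, d$groups, model = "lda", k = 6,
                               n_perm = 99, seed = 4)
  expect_true(all(res$table$accuracy == 1))
  expect_true(all(res$table$p_corrected == 1 / 100))
  # determinism: same config + seed reproduces folds and scores
  res2 <- decode_single_feature(d$x, d$y, d$groups, model = "lda", k = 6,
                                n_perm = 99, seed = 4)
  expect_identical(res$folds, res2$folds)
  expect_identical(res$table, res2$table)
})

test_that("label-independent features decode at chance with null p-values", {
  d <- paired_xy(20, 4, effect = 0, seed = 5)
  for (mod in c("lda", "svm_rbf")) {
    res <- decode_single_feature(d$x, d$y, d$groups, model = mod, k = 10,
                                 n_perm = 49, seed = 6)
    expect_lt(abs(mean(res$table$accuracy) - 0.5), 0.1)
    expect_gte(mean(res$table$p_corrected > 0.05), 0.95)
  }
})

test_that("balanced accuracy is 0.5 for a constant classifier under imbalance", {
  # identical feature values force a majority-class LDA: recalls 1 and 0;
  # the 7:3 imbalance is within every subject so all folds see both classes
  n <- 200
  y <- factor(rep(rep(c("caffeine", "placebo"), times = c(7, 3)), 20))
  groups <- rep(sprintf("s%02d", 1:20), each = 10)
  x <- rep(1, n)
  res <- decode_single_epoch(x, y, groups, k = 5, seed = 7)
  expect_equal(res$balanced_accuracy, 0.5)
})

test_that("single-epoch LDA approaches the Gaussian Bayes rate", {
  set.seed(8)
  n <- 5000
  y <- factor(rep(c("caffeine", "placebo"), each = n / 2))
  x <- rnorm(n, mean = ifelse(y == "caffeine", 1, -1))
  groups <- rep(sprintf("s%02d", 1:20), length.out = n)
  res <- decode_single_epoch(x, y, groups, k = 10, seed = 9)
  expect_lt(abs(res$balanced_accuracy - pnorm(1)), 0.03)
  # chance level on label-independent epochs
  x0 <- rnorm(n)
  res0 <- decode_single_epoch(x0, y, groups, k = 10, seed = 10)
  expect_lt(abs(res0$balanced_accuracy - 0.5), 0.05)
})

test_that("balanced accuracy equals accuracy on balanced folds", {
  set.seed(11)
  n_subj <- 12
  d <- paired_xy(n_subj, 1, effect = 0.8, seed = 11)
  folds <- grouped_kfold(d$groups, k = 4, seed = 12)
  acc <- sleepcrit:::cv_score_1d(d$x[, 1], d$y, folds, "lda")
  bacc <- sleepcrit:::cv_score_1d(d$x[, 1], d$y, folds, "lda",
                                  balanced = TRUE)
  expect_equal(acc, bacc)
})

test_that("the random forest recovers a planted single-feature signal", {
  set.seed(13)
  n_subj <- 14
  subj <- sprintf("s%02d", seq_len(n_subj))
  y <- factor(rep(c("caffeine", "placebo"), each = n_subj))
  groups <- rep(subj, 2)
  p <- 22
  x <- matrix(rnorm(2 * n_subj * p), ncol = p)
  colnames(x) <- paste0(rep(c("lzc", "delta"), each = p / 2), ".ch",
                        seq_len(p))
  x[y == "caffeine", 1:3] <- x[y == "caffeine", 1:3] + 2  # planted lzc block
  grid <- data.frame(num_trees = 100, max_depth = 5, mtry = 5)
  res <- rf_multifeature(x, y, groups, n_repeats = 6, n_holdout = 3,
                         inner_k = 3, grid = grid, seed = 14)
  expect_gt(res$accuracy_mean, 0.7)
  imp <- res$importance
  expect_gt(sum(imp$mean[1:3]), 0.5)  # planted columns dominate
  expect_equal(sum(imp$mean), 1, tolerance = 1e-9)
  # shuffled labels decode at chance
  y_null <- factor(sample(as.character(y)))
  res0 <- rf_multifeature(x, y_null, groups, n_repeats = 6, n_holdout = 3,
                          inner_k = 3, grid = grid, seed = 15)
  expect_lt(abs(res0$accuracy_mean - 0.5), 0.2)
})
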