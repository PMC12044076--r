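#' Grouped k-fold assignment
#'
#' Assigns whole groups (subjects) to folds so that all samples of one
#' subject — both recordings in the paired design — always share a fold,
#' preventing identity leakage between training and test sets.
#'
#' @param groups vector of group labels, one per sample.
#' @param k number of folds (must not exceed the number of groups).
#' @param seed integer seed for the group shuffle.
#' @return Integer fold id per sample.
#' @export
grouped_kfold <- function(groups, k = 10, seed = 1) {
  ug <- unique(groups)
  if (k > length(ug)) stop("more folds than groups")
  shuffled <- with_seed(seed, sample(ug))
  fold_of_group <- stats::setNames(rep(seq_len(k), length.out = length(ug)),
                                   shuffled)
  unname(fold_of_group[as.character(groups)])
}

# Fit + predict one fold for a single-feature classifier. Degenerate
# single-class training folds yield a constant classifier.
fit_predict_1d <- function(x_tr, y_tr, x_te, model) {
  if (length(unique(y_tr)) < 2)
    return(factor(rep(y_tr[1], length(x_te)), levels = levels(y_tr)))
  if (model == "svm_rbf") {
    fit <- e1071::svm(matrix(x_tr, ncol = 1), y_tr, kernel = "radial",
                      cost = 1, gamma = 1 / max(stats::var(x_tr), 1e-12),
                      scale = FALSE)
    stats::predict(fit, matrix(x_te, ncol = 1))
  } else {
    if (stats::sd(x_tr) == 0 ||
        any(tapply(x_tr, y_tr, stats::sd) == 0, na.rm = TRUE)) {
      maj <- names(which.max(table(y_tr)))
      return(factor(rep(maj, length(x_te)), levels = levels(y_tr)))
    }
    fit <- MASS::lda(matrix(x_tr, ncol = 1), grouping = y_tr)
    stats::predict(fit, matrix(x_te, ncol = 1))$class
  }
}

cv_score_1d <- function(x, y, folds, model, balanced = FALSE) {
  scores <- vapply(sort(unique(folds)), function(fd) {
    tr <- folds != fd
    pred <- fit_predict_1d(x[tr], y[tr], x[!tr], model)
    truth <- y[!tr]
    if (balanced) {
      if (length(unique(truth)) < 2) stop("a fold is missing one class")
      mean(vapply(levels(y), function(cl)
        mean(pred[truth == cl] == cl), numeric(1)))
    } else {
      mean(pred == truth)
    }
  }, numeric(1))
  mean(scores)
}

#' Single-feature per-channel decoding with permutation significance
#'
#' For each channel, trains a classifier (RBF-kernel SVM or LDA) on one
#' z-scored subject-level feature and scores it by grouped k-fold
#' cross-validation (average accuracy across folds). Significance comes
#' from a permutation null in which the two condition labels are swapped
#' within a random subset of subjects (respecting the paired design) and
#' the full cross-validation is re-run; corrected p-values use the maximum
#' accuracy across channels per permutation.
#'
#' @param x samples x channel matrix of one feature (rows = subject x
#'   condition samples).
#' @param y condition factor (two levels), one per row.
#' @param groups subject id per row.
#' @param model `"svm_rbf"` or `"lda"`.
#' @param k folds for the grouped cross-validation (default 10).
#' @param n_perm label permutations (default 1000; 0 skips inference).
#' @param seed integer seed (folds and permutations).
#' @return Object of class `decoding_result`: tibble `table` with
#'   per-channel `accuracy` and `p_corrected`, plus the fold assignment.
#' @export
decode_single_feature <- function(x, y, groups, model = c("svm_rbf", "lda"),
                                  k = 10, n_perm = 1000, seed = 1) {
  model <- match.arg(model)
  y <- droplevels(factor(y))
  if (nlevels(y) != 2) stop("`y` must have exactly two classes")
  folds <- grouped_kfold(groups, k, derive_seed(seed, 0))
  acc <- vapply(seq_len(ncol(x)), function(ch)
    cv_score_1d(x[, ch], y, folds, model), numeric(1))
  p <- rep(NA_real_, ncol(x))
  if (n_perm > 0) {
    ug <- unique(groups)
    max_acc <- with_seed(derive_seed(seed, 1), {
      vapply(seq_len(n_perm), function(i) {
        swap <- ug[sample(c(TRUE, FALSE), length(ug), replace = TRUE)]
        yp <- y
        flip <- groups %in% swap
        yp[flip] <- factor(levels(y)[3 - as.integer(y[flip])],
                           levels = levels(y))
        max(vapply(seq_len(ncol(x)), function(ch)
          cv_score_1d(x[, ch], yp, folds, model), numeric(1)))
      }, numeric(1))
    })
    p <- vapply(acc, function(a)
      (1 + sum(max_acc >= a - 1e-12)) / (n_perm + 1), numeric(1))
  }
  channels <- colnames(x)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(x)))
  structure(list(table = tibble::tibble(channel = channels, accuracy = acc,
                                        p_corrected = p),
                 folds = folds, model = model, n_perm = n_perm, seed = seed),
            class = "decoding_result")
}

#' Single-epoch LDA decoding with balanced accuracy
#'
#' Fits an LDA classifier on epoch-level values of one feature/channel and
#' scores it with balanced accuracy (mean of per-class recalls, which is
#' 0.5 for any constant classifier on two classes regardless of class
#' imbalance), averaged over grouped k-fold cross-validation.
#'
#' @param x numeric vector of epoch-level feature values.
#' @param y condition factor per epoch.
#' @param groups subject id per epoch.
#' @param k folds (default 10).
#' @param seed integer seed.
#' @return List with `balanced_accuracy` and the fold assignment.
#' @export
decode_single_epoch <- function(x, y, groups, k = 10, seed = 1) {
  y <- droplevels(factor(y))
  if (nlevels(y) != 2) stop("`y` must have exactly two classes")
  folds <- grouped_kfold(groups, k, derive_seed(seed, 0))
  list(balanced_accuracy = cv_score_1d(x, y, folds, "lda", balanced = TRUE),
       folds = folds)
}

#' Default random-forest hyperparameter grid
#'
#' Trees x depth x mtry fraction; a small standard grid spanning the
#' bias/variance range.
#' @param p number of features (for the mtry column).
#' @return Data frame of grid rows.
#' @export
rf_default_grid <- function(p) {
  expand.grid(num_trees = c(100, 300), max_depth = c(0, 5, 10),
              mtry = unique(pmax(1, round(c(sqrt(p), 0.2 * p)))))
}

rf_fit <- function(x, y, par, seed) {
  ranger::ranger(x = x, y = y, num.trees = par$num_trees,
                 max.depth = if (par$max_depth == 0) NULL else par$max_depth,
                 mtry = par$mtry, importance = "impurity",
                 seed = seed, num.threads = 1)
}

#' Multi-feature random-forest decoding with nested grouped CV
#'
#' Outer loop: leave out all samples of 5 random subjects as the test set.
#' Inner loop: grouped 7-fold cross-validated grid search over the
#' hyperparameter grid on the remaining subjects. The selected model is
#' refit on all training subjects and scored on the left-out subjects;
#' impurity feature importances (normalized to sum to 1 per fitted model)
#' are averaged over `n_repeats` repetitions.
#'
#' @param x samples x features matrix (e.g. 220 columns from
#'   [feature_matrix()]).
#' @param y condition factor per row.
#' @param groups subject id per row.
#' @param n_repeats outer repetitions (default 25; the full-scale analysis
#'   uses 1000).
#' @param n_holdout subjects left out per repetition (default 5).
#' @param inner_k inner folds for the grid search (default 7).
#' @param grid hyperparameter data frame (default [rf_default_grid()]).
#' @param seed integer seed.
#' @return Object of class `rf_importance_result`: `importance` tibble
#'   (feature, mean, sd, rank), `accuracy_mean`, `accuracy_sd`, per-repeat
#'   scores.
#' @export
rf_multifeature <- function(x, y, groups, n_repeats = 25, n_holdout = 5,
                            inner_k = 7, grid = NULL, seed = 1) {
  y <- droplevels(factor(y))
  if (nlevels(y) != 2) stop("`y` must have exactly two classes")
  ug <- unique(groups)
  if (length(ug) < n_holdout + inner_k)
    stop("not enough subjects for the nested scheme")
  if (is.null(grid)) grid <- rf_default_grid(ncol(x))
  imp <- matrix(0, n_repeats, ncol(x))
  acc <- numeric(n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    sd_rep <- derive_seed(seed, rep_i)
    test_subj <- with_seed(sd_rep, sample(ug, n_holdout))
    te <- groups %in% test_subj
    x_tr <- x[!te, , drop = FALSE]; y_tr <- y[!te]; g_tr <- groups[!te]
    inner_folds <- grouped_kfold(g_tr, inner_k, derive_seed(sd_rep, 1))
    grid_scores <- vapply(seq_len(nrow(grid)), function(gi) {
      mean(vapply(sort(unique(inner_folds)), function(fd) {
        tr <- inner_folds != fd
        fit <- rf_fit(x_tr[tr, , drop = FALSE], y_tr[tr], grid[gi, ],
                      derive_seed(sd_rep, 100 + gi))
        mean(stats::predict(fit, x_tr[!tr, , drop = FALSE],
                            num.threads = 1)$predictions == y_tr[!tr])
      }, numeric(1)))
    }, numeric(1))
    best <- grid[which.max(grid_scores), ]
    fit <- rf_fit(x_tr, y_tr, best, derive_seed(sd_rep, 2))
    acc[rep_i] <- mean(stats::predict(fit, x[te, , drop = FALSE],
                                      num.threads = 1)$predictions == y[te])
    iv <- pmax(0, ranger::importance(fit))
    imp[rep_i, ] <- iv / sum(iv)
  }
  imp_mean <- colMeans(imp)
  structure(list(
    importance = tibble::tibble(feature = colnames(x), mean = imp_mean,
                                sd = apply(imp, 2, stats::sd),
                                rank = rank(-imp_mean, ties.method = "first")),
    accuracy_mean = mean(acc), accuracy_sd = stats::sd(acc),
    per_repeat_accuracy = acc, n_repeats = n_repeats, seed = seed),
    class = "rf_importance_result")
}
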