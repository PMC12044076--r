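#' Paired permutation pseudo-T test with maximum-statistic correction
#'
#' For paired condition values (subject x channel matrices), computes the
#' per-channel pseudo-T statistic `mean(d) / (SE(d) + eps)` of the paired
#' differences `d = a - b`, where the regularization
#' `eps = 0.1 * median(SE)` across channels stabilizes near-zero-variance
#' channels. The null distribution is built by random sign flips of each
#' subject's whole difference vector (flips are applied jointly across
#' channels, preserving the spatial correlation structure), and each
#' permutation contributes the maximum of |T| across channels, giving
#' strong family-wise error control for the two-sided corrected p-values.
#' With `n_subjects <= 14` the sign-flip null is enumerated exhaustively;
#' otherwise `n_perm` Monte-Carlo draws with add-one p-values are used.
#'
#' @param values_a,values_b numeric subject x channel matrices with
#'   matching dimensions (e.g. caffeine and placebo).
#' @param n_perm number of Monte-Carlo sign flips (default 10000, >= 100).
#' @param seed integer seed.
#' @param epsilon pseudo-T regularization; default `0.1 * median(SE)`.
#'   Use `0` for a plain paired t statistic.
#' @return Object of class `paired_test_result`: tibble `table` with
#'   per-channel `pseudo_t`, `p_corrected`, `cohens_d`, plus `n_perm`,
#'   `exhaustive` and `seed`.
#' @export
paired_perm_pseudo_t <- function(values_a, values_b, n_perm = 10000,
                                 seed = 1, epsilon = NULL) {
  if (!all(dim(values_a) == dim(values_b)))
    stop("condition matrices must have identical dimensions")
  n <- nrow(values_a); n_ch <- ncol(values_a)
  if (n < 5) stop("need at least 5 subjects")
  if (n_perm < 100) stop("`n_perm` must be >= 100")
  d <- values_a - values_b
  ss <- colSums(d^2)
  mu <- colMeans(d)
  se <- sqrt(pmax(0, (ss - n * mu^2) / (n - 1)) / n)
  if (is.null(epsilon)) epsilon <- 0.1 * stats::median(se)
  t_obs <- mu / (se + epsilon)
  t_obs[is.nan(t_obs)] <- 0  # 0/0: no difference, no variance

  exhaustive <- n <= 14
  signs <- if (exhaustive) {
    m <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    dimnames(m) <- NULL
    m
  } else {
    with_seed(seed, matrix(sample(c(-1, 1), n_perm * n, replace = TRUE),
                           n_perm, n))
  }
  m_perm <- (signs %*% d) / n
  var_perm <- sweep(-n * m_perm^2, 2, ss, `+`) / (n - 1)
  t_perm <- abs(m_perm) / (sqrt(pmax(0, var_perm) / n) + epsilon)
  t_perm[is.nan(t_perm)] <- 0
  max_stat <- apply(t_perm, 1, max)
  p <- if (exhaustive) {
    vapply(abs(t_obs), function(t0) mean(max_stat >= t0 - 1e-12), numeric(1))
  } else {
    vapply(abs(t_obs), function(t0)
      (1 + sum(max_stat >= t0 - 1e-12)) / (nrow(signs) + 1), numeric(1))
  }
  channels <- colnames(values_a)
  if (is.null(channels)) channels <- paste0("ch", seq_len(n_ch))
  sdd <- apply(d, 2, stats::sd)
  d_eff <- ifelse(sdd > 1e-10 * apply(abs(d), 2, max),
                  mu / sdd, NA_real_)  # NA on zero-SD channels
  structure(list(
    table = tibble::tibble(channel = channels, pseudo_t = unname(t_obs),
                           p_corrected = unname(p),
                           cohens_d = unname(d_eff)),
    n_perm = nrow(signs), exhaustive = exhaustive, seed = seed,
    epsilon = epsilon), class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("<paired_test_result> %d channels, %s null (%d permutations)\n",
              nrow(x$table), if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              x$n_perm))
  print(x$table)
  invisible(x)
}

#' Paired Cohen's d per channel
#'
#' `mean(d) / sd(d)` of the paired differences `d = a - b`.
#'
#' @inheritParams paired_perm_pseudo_t
#' @return Numeric vector, one effect size per channel.
#' @export
cohens_d_paired <- function(values_a, values_b) {
  if (!all(dim(values_a) == dim(values_b)))
    stop("condition matrices must have identical dimensions")
  d <- values_a - values_b
  sdd <- apply(d, 2, stats::sd)
  # treat SDs at rounding-noise level (relative to the values) as zero
  tol <- 1e-10 * apply(abs(d), 2, max)
  if (any(sdd <= tol)) stop("zero SD of paired differences in some channel")
  unname(colMeans(d) / sdd)
}

#' Independent age-group contrast of paired condition differences
#'
#' Welch two-sample t-test per channel comparing the paired
#' caffeine-placebo differences of the young group against those of the
#' middle-aged group, with Benjamini-Hochberg FDR correction across
#' channels and significance markers at 0.05 and 0.01.
#'
#' @param diff_young,diff_middle subject x channel matrices of paired
#'   differences per age group (>= 3 subjects each).
#' @return Object of class `age_contrast_result` with a per-channel tibble
#'   `table` (`t`, `p`, `p_fdr`, `sig05`, `sig01`) and the group sizes.
#' @export
age_contrast <- function(diff_young, diff_middle) {
  if (ncol(diff_young) != ncol(diff_middle))
    stop("channel counts differ between groups")
  if (nrow(diff_young) < 3 || nrow(diff_middle) < 3)
    stop("need >= 3 subjects per group")
  res <- vapply(seq_len(ncol(diff_young)), function(ch) {
    tt <- stats::t.test(diff_young[, ch], diff_middle[, ch])
    c(tt$statistic, tt$p.value)
  }, numeric(2))
  p_fdr <- stats::p.adjust(res[2, ], method = "BH")
  channels <- colnames(diff_young)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(diff_young)))
  structure(list(
    table = tibble::tibble(channel = channels, t = unname(res[1, ]),
                           p = unname(res[2, ]), p_fdr = p_fdr,
                           sig05 = p_fdr < 0.05, sig01 = p_fdr < 0.01),
    n_young = nrow(diff_young), n_middle = nrow(diff_middle)),
    class = "age_contrast_result")
}

#' Subject x channel matrix of one feature from a subject-level table
#'
#' @param subject_table subject-level feature table.
#' @param feature feature column name.
#' @param condition condition to extract.
#' @return Matrix with one row per subject (sorted by id), one column per
#'   channel.
#' @export
feature_matrix_by_condition <- function(subject_table, feature, condition) {
  sub <- subject_table[subject_table$condition == condition, ]
  subjects <- sort(unique(sub$subject_id))
  channels <- unique(sub$channel)
  m <- matrix(NA_real_, length(subjects), length(channels),
              dimnames = list(subjects, channels))
  for (i in seq_along(subjects)) {
    rows <- sub[sub$subject_id == subjects[i], ]
    m[i, ] <- rows[[feature]][match(channels, rows$channel)]
  }
  m
}
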