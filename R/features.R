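#' The 11 canonical features
#'
#' Five 1/f-corrected band powers, spectral entropy, sample entropy,
#' spectral sample entropy, normalized Lempel-Ziv complexity, the DFA
#' scaling exponent and the aperiodic slope.
#' @export
canonical_features <- c("delta", "theta", "alpha", "sigma", "beta",
                        "specen", "sampen", "specsampen", "lzc",
                        "dfa_alpha", "slope")

#' Extract per-epoch features from a recording
#'
#' Computes every canonical feature for each epoch of the requested sleep
#' stage and each channel: Welch PSD per epoch, an aperiodic fit per
#' channel feeding the corrected band powers and the slope feature, the
#' three entropy metrics, Lempel-Ziv complexity and DFA. Metric failures
#' on degenerate epochs (zero variance, no entropy matches) are recorded
#' as `NA`/`Inf` flagged cells, never as errors; spectral cells of such
#' epochs are still computed when possible.
#'
#' @param rec a preprocessed [epoched_recording()].
#' @param stage `"NREM"` or `"REM"`.
#' @param include_permen also compute permutation entropy as an extra
#'   column (default FALSE; not part of the canonical set).
#' @param fit_args extra arguments passed to [fit_aperiodic()].
#' @return Epoch-level feature tibble keyed by (subject_id, condition,
#'   age_group, stage, channel, epoch_index) with one column per feature.
#' @export
extract_features <- function(rec, stage = "NREM", include_permen = FALSE,
                             fit_args = list()) {
  stopifnot(inherits(rec, "epoched_recording"))
  stage <- match.arg(stage, c("NREM", "REM"))
  eps <- which(rec$stage_labels == stage)
  if (length(eps) == 0) stop(sprintf("no %s epochs in recording", stage))
  n_ch <- length(rec$channel_names)
  rows <- vector("list", length(eps) * n_ch)
  k <- 0L
  safely <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  for (e in eps) {
    seg <- rec$epochs[e, , , drop = TRUE]
    if (is.null(dim(seg))) seg <- matrix(seg, nrow = 1)
    ps <- welch_psd(seg, rec$fs, channel_names = rec$channel_names)
    for (ch in seq_len(n_ch)) {
      x <- seg[ch, ]
      mod <- tryCatch(do.call(fit_aperiodic, c(list(ps, ch), fit_args)),
                      error = function(e) NULL)
      bp <- if (!is.null(mod))
        safely(corrected_band_power(ps, mod, ch))
      else
        stats::setNames(rep(NA_real_, 5), names(eeg_bands))
      if (length(bp) == 1 && is.na(bp))
        bp <- stats::setNames(rep(NA_real_, 5), names(eeg_bands))
      row <- tibble::tibble(
        subject_id = rec$subject_id, condition = rec$condition,
        age_group = rec$age_group, stage = stage,
        channel = rec$channel_names[ch], epoch_index = e,
        delta = bp[["delta"]], theta = bp[["theta"]], alpha = bp[["alpha"]],
        sigma = bp[["sigma"]], beta = bp[["beta"]],
        specen = safely(spectral_entropy(ps, ch)),
        sampen = safely(sample_entropy(x)),
        specsampen = safely(spectral_sample_entropy(ps, ch)),
        lzc = safely(lempel_ziv(x)),
        dfa_alpha = safely(dfa(x)$alpha),
        slope = if (is.null(mod)) NA_real_ else slope_feature(mod))
      if (include_permen) row$permen <- safely(permutation_entropy(x))
      k <- k + 1L
      rows[[k]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "level") <- "epoch"
  out
}

feature_cols <- function(tab) intersect(c(canonical_features, "permen"),
                                        names(tab))

#' Average epoch-level features within subject
#'
#' Arithmetic mean over valid (finite) epochs for every (subject,
#' condition, stage, channel) cell; flagged cells (`NA`, `Inf`) are
#' excluded from the mean. Errors if any cell has no valid epoch at all.
#'
#' @param epoch_table an epoch-level table from [extract_features()].
#' @return Subject-level feature tibble (one row per subject x condition x
#'   stage x channel).
#' @export
average_by_subject <- function(epoch_table) {
  fc <- feature_cols(epoch_table)
  out <- epoch_table |>
    dplyr::group_by(.data$subject_id, .data$condition, .data$age_group,
                    .data$stage, .data$channel) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(fc), function(v) {
      v <- v[is.finite(v)]
      if (length(v) == 0) return(NaN)
      mean(v)
    }), .groups = "drop")
  if (any(vapply(out[fc], function(v) any(is.nan(v)), logical(1))))
    stop("a (subject, channel) cell has zero valid epochs")
  attr(out, "level") <- "subject"
  out
}

#' Within-subject z-transform of feature tables
#'
#' For each subject and feature, the mean and SD are computed from that
#' subject's epoch-level values pooled across all channels, epochs and
#' both conditions, and the target table's values are transformed as
#' `(v - mu) / sd`. No cross-subject quantity enters any subject's
#' transform, so train/test independence in grouped cross-validation is
#' preserved by construction.
#'
#' @param table the table to transform (subject- or epoch-level).
#' @param epoch_table the epoch-level table supplying the statistics
#'   (default: `table` itself).
#' @return The transformed table (attribute `zscored = TRUE`).
#' @export
z_transform <- function(table, epoch_table = table) {
  fc <- feature_cols(table)
  stats_tab <- epoch_table |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(fc), list(
      mu = function(v) mean(v[is.finite(v)]),
      sd = function(v) stats::sd(v[is.finite(v)]))), .groups = "drop")
  for (f in fc) {
    if (any(!is.finite(stats_tab[[paste0(f, "_sd")]])) ||
        any(stats_tab[[paste0(f, "_sd")]] == 0))
      stop(sprintf("zero or undefined SD for feature `%s` in some subject", f))
  }
  out <- table
  idx <- match(out$subject_id, stats_tab$subject_id)
  if (any(is.na(idx))) stop("epoch-level statistics missing for some subject")
  for (f in fc) {
    mu <- stats_tab[[paste0(f, "_mu")]][idx]
    sdv <- stats_tab[[paste0(f, "_sd")]][idx]
    out[[f]] <- (out[[f]] - mu) / sdv
  }
  attr(out, "level") <- attr(table, "level")
  attr(out, "zscored") <- TRUE
  out
}

#' Reshape a subject-level table into a samples x (feature, channel) matrix
#'
#' One row per subject x condition; one column per (feature, channel)
#' pair, named `feature.channel`. This is the input layout of the
#' multi-feature classifier (11 features x 20 channels = 220 columns for
#' the default montage).
#'
#' @param subject_table subject-level feature table.
#' @param features feature columns to include (default [canonical_features]).
#' @return List with `x` (matrix), `y` (condition factor), `groups`
#'   (subject ids), `meta` (tibble of row metadata).
#' @export
feature_matrix <- function(subject_table, features = canonical_features) {
  stopifnot(all(features %in% names(subject_table)))
  meta <- subject_table |>
    dplyr::distinct(.data$subject_id, .data$condition, .data$age_group,
                    .data$stage)
  channels <- unique(subject_table$channel)
  cn <- as.vector(vapply(channels, function(ch)
    paste(features, ch, sep = "."), character(length(features))))
  x <- matrix(NA_real_, nrow(meta), length(cn), dimnames = list(NULL, cn))
  for (i in seq_len(nrow(meta))) {
    sub <- subject_table[subject_table$subject_id == meta$subject_id[i] &
                           subject_table$condition == meta$condition[i], ]
    x[i, ] <- as.vector(vapply(channels, function(ch)
      unlist(sub[sub$channel == ch, features]), numeric(length(features))))
  }
  list(x = x, y = factor(meta$condition, levels = c("placebo", "caffeine")),
       groups = meta$subject_id, meta = meta)
}
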