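#' Epoched EEG recording
#'
#' Container for one subject/condition night of sleep EEG, segmented into
#' fixed-length epochs. Signals are stored as an epoch x channel x sample
#' array in microvolts, together with one sleep-stage label per epoch
#' (`"NREM"`, `"REM"` or `"artifact"`; finer NREM stages S1-S4 are collapsed
#' to `"NREM"` on read).
#'
#' @param epochs numeric array, epoch x channel x sample (microvolts).
#' @param stage_labels character vector, one of `"NREM"`, `"REM"`,
#'   `"artifact"` per epoch.
#' @param fs sampling rate in Hz.
#' @param channel_names character vector of 10-20 montage labels.
#' @param subject_id subject identifier.
#' @param condition `"caffeine"` or `"placebo"`.
#' @param age_group `"young"` or `"middle"`.
#' @param epoch_len epoch length in seconds (default 20).
#'
#' @return An object of class `epoched_recording`.
#' @export
epoched_recording <- function(epochs, stage_labels, fs, channel_names,
                              subject_id = "s01", condition = "placebo",
                              age_group = "young", epoch_len = 20) {
  if (length(dim(epochs)) != 3L)
    stop("`epochs` must be a 3-d array (epoch x channel x sample)")
  stopifnot_scalar(fs, "fs")
  if (fs <= 0) stop("`fs` must be positive")
  n_samp <- round(fs * epoch_len)
  if (dim(epochs)[3] != n_samp)
    stop(sprintf("samples per epoch must equal fs * epoch_len = %d", n_samp))
  if (dim(epochs)[2] != length(channel_names))
    stop("channel count must match length of `channel_names`")
  if (dim(epochs)[1] != length(stage_labels))
    stop("`stage_labels` must have one entry per epoch")
  stage_labels <- as.character(stage_labels)
  bad <- setdiff(unique(stage_labels), c("NREM", "REM", "artifact"))
  if (length(bad))
    stop("unknown stage labels: ", paste(bad, collapse = ", "))
  if (!all(is.finite(epochs))) stop("all sample values must be finite")
  condition <- match.arg(condition, c("caffeine", "placebo"))
  age_group <- match.arg(age_group, c("young", "middle"))
  structure(
    list(epochs = epochs, stage_labels = stage_labels, fs = fs,
         channel_names = as.character(channel_names),
         subject_id = as.character(subject_id), condition = condition,
         age_group = age_group, epoch_len = epoch_len),
    class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  tab <- table(factor(x$stage_labels, levels = c("NREM", "REM", "artifact")))
  cat(sprintf("<epoched_recording> subject %s, %s (%s)\n", x$subject_id,
              x$condition, x$age_group))
  cat(sprintf("  %d epochs x %d channels x %d samples @ %g Hz (%g s epochs)\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3], x$fs,
              x$epoch_len))
  cat(sprintf("  stages: NREM %d, REM %d, artifact %d\n",
              tab[["NREM"]], tab[["REM"]], tab[["artifact"]]))
  invisible(x)
}

# Subset a recording to a set of epoch indices, keeping metadata.
subset_epochs <- function(rec, idx) {
  epoched_recording(rec$epochs[idx, , , drop = FALSE], rec$stage_labels[idx],
                    rec$fs, rec$channel_names, rec$subject_id, rec$condition,
                    rec$age_group, rec$epoch_len)
}

#' Number of epochs per sleep stage
#'
#' @param rec an [epoched_recording()].
#' @return Named integer vector with counts for NREM, REM and artifact epochs.
#' @export
stage_counts <- function(rec) {
  tab <- table(factor(rec$stage_labels, levels = c("NREM", "REM", "artifact")))
  stats::setNames(as.integer(tab), names(tab))
}
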