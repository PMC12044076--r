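#' Zero-phase band-pass filter an epoched recording
#'
#' 4th-order Butterworth applied forward-backward (`signal::filtfilt`) to
#' each epoch and channel independently, so filtering never mixes data
#' across epoch boundaries and introduces no phase lag (waveform timing is
#' preserved for the entropy metrics downstream).
#'
#' @param rec an [epoched_recording()].
#' @param low,high band edges in Hz (defaults 0.5 and 32).
#' @param order Butterworth order (default 4).
#' @return A filtered [epoched_recording()].
#' @export
bandpass <- function(rec, low = 0.5, high = 32, order = 4) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop("band edges must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  out <- rec$epochs
  for (e in seq_len(dim(out)[1]))
    for (ch in seq_len(dim(out)[2]))
      out[e, ch, ] <- signal::filtfilt(bf, rec$epochs[e, ch, ])
  rec$epochs <- out
  rec
}

#' Drop epochs whose amplitude exceeds a fixed threshold
#'
#' A reproducible automated surrogate for visual artifact rejection: any
#' epoch in which any channel exceeds `threshold` microvolts in absolute
#' value is removed. Epoch order is preserved.
#'
#' @param rec an [epoched_recording()].
#' @param threshold absolute amplitude threshold in microvolts (default 300).
#' @return An [epoched_recording()] with offending epochs removed.
#' @export
reject_artifact_epochs <- function(rec, threshold = 300) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (threshold <= 0) stop("`threshold` must be positive")
  peak <- apply(abs(rec$epochs), 1, max)
  keep <- which(peak <= threshold)
  if (length(keep) == 0) stop("all epochs rejected")
  subset_epochs(rec, keep)
}

#' Equate epoch counts of one stage across two paired recordings
#'
#' Randomly subsamples (without replacement) the condition with more epochs
#' of `stage` so both recordings contribute `min(n1, n2)` epochs of that
#' stage; all other epochs are left untouched. Used as the sleep-duration
#' control: with equal epoch counts, condition differences cannot be an
#' artifact of unequal averaging noise.
#'
#' @param rec_a,rec_b paired [epoched_recording()]s (same subject, two
#'   conditions).
#' @param stage `"NREM"` or `"REM"`.
#' @param seed integer seed for the subsampling.
#' @return List with elements `a` and `b`, the equated recordings.
#' @export
equate_epoch_counts <- function(rec_a, rec_b, stage = "NREM", seed = 1) {
  stage <- match.arg(stage, c("NREM", "REM"))
  ia <- which(rec_a$stage_labels == stage)
  ib <- which(rec_b$stage_labels == stage)
  if (length(ia) == 0 || length(ib) == 0)
    stop(sprintf("no %s epochs in one of the recordings", stage))
  n <- min(length(ia), length(ib))
  keep <- function(rec, idx, which_seed) {
    if (length(idx) == n) return(rec)   # smaller side untouched
    sel <- sort(with_seed(which_seed, sample(idx, n)))
    drop <- setdiff(idx, sel)
    subset_epochs(rec, setdiff(seq_along(rec$stage_labels), drop))
  }
  list(a = keep(rec_a, ia, derive_seed(seed, 1)),
       b = keep(rec_b, ib, derive_seed(seed, 2)))
}
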