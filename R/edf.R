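#' @title Minimal EDF (European Data Format) input/output
#' @description 16-bit EDF reader/writer sufficient for continuous
#'   polysomnography exports: fixed-width ASCII header, one sampling rate
#'   across channels, int16 little-endian data records. Signals round-trip
#'   to within the 16-bit quantization of the per-channel physical range.
#' @name edf-io
NULL

pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

# render a number into at most 8 ASCII characters (EDF header field)
num8 <- function(v) {
  for (digits in 7:1) {
    s <- formatC(signif(v, digits), format = "g", digits = digits)
    if (nchar(s) <= 8) return(pad(s, 8))
  }
  stop("cannot render value in 8 characters")
}

#' Write an epoched recording to EDF plus a hypnogram sidecar
#'
#' Epochs are written back-to-back as EDF data records of `epoch_len`
#' seconds; the hypnogram is a TSV with columns `epoch_index` (0-based) and
#' `stage`.
#'
#' @param rec an [epoched_recording()].
#' @param edf_path output EDF file path.
#' @param hypnogram_path output TSV path (default: `edf_path` with
#'   `.hypnogram.tsv` appended); `NULL` to skip.
#' @return Invisibly, `edf_path`.
#' @export
write_recording <- function(rec, edf_path,
                            hypnogram_path = paste0(edf_path, ".hypnogram.tsv")) {
  stopifnot(inherits(rec, "epoched_recording"))
  n_epoch <- dim(rec$epochs)[1]; n_chan <- dim(rec$epochs)[2]
  n_samp <- dim(rec$epochs)[3]
  # symmetric physical range per channel, padded to avoid clipping
  pmax_ch <- vapply(seq_len(n_chan), function(ch)
    max(1e-6, max(abs(rec$epochs[, ch, ]))), numeric(1)) * 1.0001
  con <- file(edf_path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * n_chan
  header <- paste0(
    pad("0", 8),
    pad(paste("X X X", rec$subject_id), 80),
    pad(paste("Startdate 01-JAN-2000", rec$condition, rec$age_group), 80),
    "01.01.00", "00.00.00",
    pad(hdr_bytes, 8), pad("", 44),
    pad(n_epoch, 8), pad(format(rec$epoch_len), 8), pad(n_chan, 4),
    paste(vapply(rec$channel_names, pad, character(1), width = 16), collapse = ""),
    paste(rep(pad("", 80), n_chan), collapse = ""),
    paste(rep(pad("uV", 8), n_chan), collapse = ""),
    paste(vapply(-pmax_ch, num8, character(1)), collapse = ""),
    paste(vapply(pmax_ch, num8, character(1)), collapse = ""),
    paste(rep(pad(-32768, 8), n_chan), collapse = ""),
    paste(rep(pad(32767, 8), n_chan), collapse = ""),
    paste(rep(pad("", 80), n_chan), collapse = ""),
    paste(rep(pad(n_samp, 8), n_chan), collapse = ""),
    paste(rep(pad("", 32), n_chan), collapse = ""))
  writeChar(header, con, nchars = nchar(header), eos = NULL)
  # re-read the header's printed physical ranges so quantization matches read
  pmin_r <- as.numeric(trimws(vapply(-pmax_ch, num8, character(1))))
  pmax_r <- as.numeric(trimws(vapply(pmax_ch, num8, character(1))))
  for (e in seq_len(n_epoch)) {
    for (ch in seq_len(n_chan)) {
      x <- rec$epochs[e, ch, ]
      dig <- round((x - pmin_r[ch]) / (pmax_r[ch] - pmin_r[ch]) * 65535 - 32768)
      dig <- pmin(pmax(dig, -32768), 32767)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  if (!is.null(hypnogram_path)) {
    utils::write.table(
      data.frame(epoch_index = seq_len(n_epoch) - 1L, stage = rec$stage_labels),
      hypnogram_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(edf_path)
}

# Parse an EDF file into a list(signal matrix [channel x sample], fs,
# channel_names, record_dur, n_records).
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd_str <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd_num <- function(n) as.numeric(rd_str(n))
  rd_str(8)                     # version
  rd_str(80); rd_str(80)        # patient / recording id
  rd_str(8); rd_str(8)          # date / time
  rd_num(8)                     # header bytes
  rd_str(44)
  n_rec <- suppressWarnings(rd_num(8))
  rec_dur <- suppressWarnings(rd_num(8))
  ns <- suppressWarnings(as.integer(rd_num(4)))
  if (anyNA(c(n_rec, rec_dur, ns)) || length(ns) != 1L || ns < 1 ||
      n_rec < 1 || rec_dur <= 0)
    stop("not a valid EDF file: ", path)
  fld <- function(w) vapply(seq_len(ns), function(i) rd_str(w), character(1))
  labels <- fld(16); fld(80); fld(8)
  pmin <- as.numeric(fld(8)); pmax <- as.numeric(fld(8))
  dmin <- as.numeric(fld(8)); dmax <- as.numeric(fld(8))
  fld(80)
  spr <- as.integer(fld(8)); fld(32)
  if (length(unique(spr)) != 1L)
    stop("EDF sampling rate must be uniform across channels")
  fs <- spr[1] / rec_dur
  sig <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2, endian = "little")
      phys <- pmin[ch] + (dig - dmin[ch]) * (pmax[ch] - pmin[ch]) / (dmax[ch] - dmin[ch])
      sig[ch, ((r - 1) * spr[ch] + 1):(r * spr[ch])] <- phys
    }
  }
  list(signal = sig, fs = fs, channel_names = labels,
       record_dur = rec_dur, n_records = n_rec)
}

# Read a hypnogram TSV (epoch_index, stage); S1-S4 collapse to NREM.
read_hypnogram <- function(path) {
  h <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("epoch_index", "stage") %in% names(h)))
    stop("hypnogram must have columns `epoch_index` and `stage`")
  st <- as.character(h$stage[order(h$epoch_index)])
  st[st %in% c("S1", "S2", "S3", "S4", "N1", "N2", "N3")] <- "NREM"
  st
}

#' Read an EDF recording with its hypnogram into an epoched recording
#'
#' The continuous signal is segmented into contiguous `epoch_len`-second
#' epochs starting at time 0; a trailing partial epoch is dropped. Finer
#' NREM hypnogram labels (S1-S4, N1-N3) are collapsed to `"NREM"`.
#' Artifact-labeled epochs are retained but flagged via their stage label.
#'
#' @param edf_path EDF file path.
#' @param hypnogram_path TSV with columns `epoch_index`, `stage`.
#' @param subject_id,condition,age_group recording metadata.
#' @param epoch_len epoch length in seconds (default 20).
#' @return An [epoched_recording()].
#' @export
read_recording <- function(edf_path, hypnogram_path, subject_id = "s01",
                           condition = "placebo", age_group = "young",
                           epoch_len = 20) {
  edf <- read_edf(edf_path)
  n_per_epoch <- as.integer(round(edf$fs * epoch_len))
  n_epoch <- floor(ncol(edf$signal) / n_per_epoch)
  if (n_epoch < 1) stop("recording shorter than one epoch")
  stages <- read_hypnogram(hypnogram_path)
  if (abs(length(stages) - n_epoch) > 1L)
    stop(sprintf("hypnogram has %d labels for %d epochs", length(stages), n_epoch))
  n_epoch <- min(n_epoch, length(stages))
  stages <- stages[seq_len(n_epoch)]
  arr <- array(0, dim = c(n_epoch, nrow(edf$signal), n_per_epoch))
  for (e in seq_len(n_epoch))
    arr[e, , ] <- edf$signal[, ((e - 1) * n_per_epoch + 1):(e * n_per_epoch)]
  epoched_recording(arr, stages, edf$fs, edf$channel_names, subject_id,
                    condition, age_group, epoch_len)
}
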