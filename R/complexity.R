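#' Sample entropy (SampEn)
#'
#' `-log(A/B)` where B counts template pairs of length `m` matching under
#' the Chebyshev (maximum) norm within tolerance `r * sd(x)`, and A those
#' still matching at length `m + 1`. Self-matches are excluded. Low values
#' indicate a predictable signal. When no template pair extends (`A = 0`)
#' the value is `+Inf`, a sentinel that downstream averaging treats as a
#' flagged (invalid) cell.
#'
#' @param x numeric vector, length >= m + 2, non-constant.
#' @param m embedding window length (default 2).
#' @param r tolerance as a fraction of `sd(x)` (default 0.2).
#' @return Nonnegative value (possibly `+Inf`).
#' @export
sample_entropy <- function(x, m = 2, r = 0.2) {
  if (m < 1) stop("`m` must be >= 1")
  if (r <= 0) stop("`r` must be positive")
  if (length(x) < m + 2) stop("`x` must have length >= m + 2")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance")
  ab <- .sampen_counts(as.numeric(x), as.integer(m), r * s)
  if (ab[2] == 0) return(Inf)
  if (ab[1] == 0) return(Inf)
  -log(ab[1] / ab[2])
}

# PSD bin values of one channel restricted to [lo, hi] Hz
psd_band_values <- function(ps, channel, lo = 0.5, hi = 32) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (is.character(channel)) channel <- match(channel, ps$channel_names)
  sel <- ps$freqs >= lo & ps$freqs <= hi
  ps$power[channel, sel]
}

#' Spectral entropy (SpecEn)
#'
#' Shannon entropy of the power spectrum normalized to a probability
#' distribution over frequency bins in 0.5-32 Hz, divided by `log(n_bins)`
#' so the value lies in [0, 1]: 0 when all power sits in a single bin, 1
#' for an exactly flat spectrum. Computed on the full, uncorrected
#' spectrum.
#'
#' @param ps a [welch_psd()] `power_spectrum`.
#' @param channel channel index or name (default 1).
#' @param range frequency range in Hz (default `c(0.5, 32)`).
#' @return Value in [0, 1].
#' @export
spectral_entropy <- function(ps, channel = 1, range = c(0.5, 32)) {
  p <- psd_band_values(ps, channel, range[1], range[2])
  if (length(p) < 2 || sum(p) <= 0) stop("need >= 2 bins with positive power")
  pr <- p / sum(p)
  pr <- pr[pr > 0]
  -sum(pr * log(pr)) / log(length(p))
}

#' Spectral sample entropy (SpecSampEn)
#'
#' Sample entropy applied to the ordered sequence of power-spectrum bin
#' values in 0.5-32 Hz (linear power), treating the spectrum as a coherent
#' signal so that local patterns across neighboring frequency bins enter
#' the complexity estimate — unlike Shannon spectral entropy, which is
#' permutation-invariant.
#'
#' @inheritParams spectral_entropy
#' @param m,r sample-entropy parameters (defaults 2 and 0.2).
#' @param log_power apply `log10` to the bin values first (default FALSE).
#' @return Nonnegative value (possibly `+Inf`).
#' @export
spectral_sample_entropy <- function(ps, channel = 1, m = 2, r = 0.2,
                                    range = c(0.5, 32), log_power = FALSE) {
  p <- psd_band_values(ps, channel, range[1], range[2])
  if (log_power) p <- log10(p)
  sample_entropy(p, m = m, r = r)
}

#' Normalized Lempel-Ziv complexity (LZc)
#'
#' The signal is binarized by a median split (strictly above the median
#' maps to 1 — a deterministic tie rule, so integer-quantized data never
#' binarize randomly), parsed into LZ76 phrases, and the phrase count
#' `c(n)` is normalized as `c(n) * log2(n) / n` (binary alphabet), making
#' the value approximately length-independent and ~1 for random sequences.
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @return Normalized complexity value.
#' @export
lempel_ziv <- function(x) {
  n <- length(x)
  if (n < 2) stop("`x` must have length >= 2")
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop("zero variance")
  b <- as.integer(x > stats::median(x))
  c_n <- .lz76_count(b)
  c_n * log2(n) / n
}

#' Permutation entropy (PermEn)
#'
#' Bandt-Pompe ordinal-pattern entropy: Shannon entropy of the empirical
#' distribution of rank patterns of `order` consecutive (delayed) samples,
#' normalized by `log(order!)` to lie in [0, 1]. Ties are broken by
#' temporal order (first occurrence ranks lower). Computed and stored as an
#' optional extra; it is not part of the 11-feature canonical set.
#'
#' @param x numeric vector.
#' @param order pattern length (default 3).
#' @param delay lag between pattern samples (default 1).
#' @return Value in [0, 1].
#' @export
permutation_entropy <- function(x, order = 3, delay = 1) {
  n <- length(x)
  if (order < 2) stop("`order` must be >= 2")
  if (n < order * delay + 1) stop("`x` too short for the requested order/delay")
  n_pat <- n - (order - 1) * delay
  idx <- outer(seq_len(n_pat), (0:(order - 1)) * delay, `+`)
  pats <- apply(matrix(x[idx], n_pat, order), 1,
                function(v) paste(order(v), collapse = ""))
  pr <- as.numeric(table(pats)) / n_pat
  -sum(pr * log(pr)) / log(factorial(order))
}
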