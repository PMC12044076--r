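#' Detrended fluctuation analysis (DFA)
#'
#' Cumulatively sums the mean-subtracted signal into a profile, splits the
#' profile into non-overlapping windows of each size, removes a linear
#' trend per window, and records the root-mean-square fluctuation F(n) as
#' a function of window size n. The scaling exponent alpha is the
#' least-squares slope of log F(n) vs log n. Alpha generalizes the Hurst
#' exponent: 0.5 for white noise, < 0.5 for anti-correlated signals,
#' > 0.5 for long-range temporal correlations, and > 1 for unbounded
#' non-stationary signals (e.g. ~1.5 for a Brownian path).
#'
#' @param x numeric vector, length >= 4 x the smallest window.
#' @param window_sizes integer window sizes in samples; default ~16
#'   log-spaced sizes from 16 to `length(x)/4`.
#' @param n_windows number of log-spaced sizes when `window_sizes` is NULL.
#' @return An object of class `dfa_result`: `alpha`, `fit_r2`, and
#'   `fluctuations` (data frame of window size and F(n)).
#' @export
dfa <- function(x, window_sizes = NULL, n_windows = 16) {
  n <- length(x)
  if (is.null(window_sizes)) {
    if (n < 64) stop("input too short for default DFA windows")
    window_sizes <- unique(round(exp(seq(log(16), log(n / 4),
                                         length.out = n_windows))))
  }
  window_sizes <- sort(unique(as.integer(window_sizes)))
  if (min(window_sizes) < 3) stop("smallest window must be >= 3 samples")
  if (max(window_sizes) > n / 4) stop("largest window must be <= length(x)/4")
  if (length(window_sizes) < 6) stop("need >= 6 distinct window sizes")
  prof <- cumsum(x - mean(x))
  t1 <- seq_len(max(window_sizes))
  fl <- vapply(window_sizes, function(w) {
    k <- floor(n / w)
    seg <- matrix(prof[seq_len(k * w)], nrow = w)          # window x segment
    tt <- t1[seq_len(w)]
    # linear detrend of every segment at once via projection
    X <- cbind(1, tt)
    H <- X %*% solve(crossprod(X), t(X))
    res <- seg - H %*% seg
    sqrt(mean(res^2))
  }, numeric(1))
  if (any(fl <= 0)) stop("zero fluctuation (constant input?)")
  lf <- log(fl); lw <- log(window_sizes)
  fit <- stats::lm(lf ~ lw)
  structure(list(alpha = unname(stats::coef(fit)[2]),
                 fit_r2 = summary(fit)$r.squared,
                 fluctuations = data.frame(window = window_sizes, F = fl)),
            class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf("<dfa_result> alpha %.3f (R^2 %.4f, %d window sizes %d-%d)\n",
              x$alpha, x$fit_r2, nrow(x$fluctuations),
              min(x$fluctuations$window), max(x$fluctuations$window)))
  invisible(x)
}

# Amplitude envelope of the analytic signal (FFT implementation of the
# Hilbert transform).
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

#' Band-limited DFA on the Hilbert amplitude envelope
#'
#' Band-pass filters the signal (zero-phase Butterworth), extracts the
#' amplitude envelope of the analytic signal, and runs [dfa()] on the
#' envelope — probing long-range temporal correlations of band-specific
#' amplitude dynamics rather than of the broadband signal. One second is
#' trimmed from each end of the envelope to discard filter transients,
#' and the default window sizes start at six envelope decorrelation times
#' (`6 * fs / bandwidth` samples): below that scale any narrowband
#' envelope is intrinsically smooth and would inflate the exponent
#' regardless of long-range structure.
#'
#' @param x numeric vector.
#' @param band `c(low, high)` in Hz, inside (0, fs/2).
#' @param fs sampling rate in Hz.
#' @param window_sizes passed to [dfa()]; default ~12 log-spaced sizes from
#'   `6 * fs / bandwidth` to a quarter of the trimmed envelope length.
#' @param order Butterworth order (default 4).
#' @param edge_trim seconds trimmed from each end of the envelope
#'   (default 1).
#' @return A `dfa_result` for the envelope.
#' @export
band_dfa <- function(x, band, fs, window_sizes = NULL, order = 4,
                     edge_trim = 1) {
  if (!(band[1] > 0 && band[1] < band[2] && band[2] < fs / 2))
    stop("band must satisfy 0 < low < high < fs/2")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  env <- hilbert_envelope(signal::filtfilt(bf, x))
  tr <- round(edge_trim * fs)
  if (length(env) > 4 * tr + 64) env <- env[(tr + 1):(length(env) - tr)]
  if (stats::sd(env) < 1e-2 * mean(abs(env)))
    stop("zero fluctuation: constant envelope (pure in-band sinusoid?)")
  if (is.null(window_sizes)) {
    minw <- max(16, round(6 * fs / (band[2] - band[1])))
    maxw <- floor(length(env) / 4)
    if (maxw <= minw * 1.5) stop("input too short for band-limited DFA")
    window_sizes <- unique(round(exp(seq(log(minw), log(maxw),
                                         length.out = 12))))
  }
  dfa(env, window_sizes = window_sizes)
}
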