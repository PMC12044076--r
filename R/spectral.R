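#' Canonical sleep-EEG frequency bands (Hz)
#'
#' delta 0.5-4, theta 4-8, alpha 8-12, sigma 12-16, beta 16-32.
#' @export
eeg_bands <- list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 12),
                  sigma = c(12, 16), beta = c(16, 32))

#' Welch power spectral density
#'
#' Hann-tapered, 50%-overlapping segments (defaults 4-s windows, 2-s
#' overlap, giving 0.25 Hz resolution and 9 averaged segments per 20-s
#' epoch), one-sided density normalization so the PSD integrates to the
#' signal variance.
#'
#' @param epoch numeric vector (one channel) or channel x sample matrix.
#' @param fs sampling rate in Hz.
#' @param window_len,overlap segment length and overlap in seconds.
#' @param channel_names optional channel labels.
#' @return An object of class `power_spectrum` with `freqs` (Hz) and
#'   `power` (channel x frequency matrix, power/Hz).
#' @export
welch_psd <- function(epoch, fs, window_len = 4, overlap = 2,
                      channel_names = NULL) {
  if (is.vector(epoch)) epoch <- matrix(epoch, nrow = 1)
  nw <- as.integer(round(window_len * fs))
  step <- as.integer(round((window_len - overlap) * fs))
  n <- ncol(epoch)
  if (n < nw) stop("epoch shorter than one Welch window")
  starts <- seq(1L, n - nw + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nw) / (nw + 1))  # Hann taper
  u <- sum(w^2)
  nf <- nw %/% 2L + 1L
  pow <- matrix(0, nrow(epoch), nf)
  for (ch in seq_len(nrow(epoch))) {
    acc <- numeric(nf)
    for (s in starts) {
      seg <- epoch[ch, s:(s + nw - 1L)]
      seg <- (seg - mean(seg)) * w
      X <- stats::fft(seg)[seq_len(nf)]
      acc <- acc + (Mod(X)^2) / (fs * u)
    }
    p <- acc / length(starts)
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]  # one-sided (not DC/Nyquist)
    pow[ch, ] <- p
  }
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(nrow(epoch)))
  structure(list(freqs = seq(0, nf - 1L) * fs / nw, power = pow,
                 window_len = window_len, overlap = overlap,
                 channel_names = channel_names),
            class = "power_spectrum")
}

gauss_sum <- function(f, peaks) {
  g <- numeric(length(f))
  if (is.null(peaks) || nrow(peaks) == 0) return(g)
  for (i in seq_len(nrow(peaks)))
    g <- g + peaks[i, 2] * exp(-(f - peaks[i, 1])^2 / (2 * peaks[i, 3]^2))
  g
}

robust_line <- function(x, y) {
  fit <- tryCatch(MASS::rlm(y ~ x, maxit = 50),
                  error = function(e) stats::lm(y ~ x),
                  warning = function(w) stats::lm(y ~ x))
  unname(stats::coef(fit))
}

#' Fit an aperiodic (1/f) model with Gaussian peaks to a power spectrum
#'
#' Iterative parameterization of the spectrum in the 3-32 Hz range:
#' a robust line fit in log10 power vs log10 frequency, then repeated
#' extraction of the largest positive residual as a Gaussian peak (center
#' in the fit range, width clipped to 0.5-12 Hz) until at most
#' `max_n_peaks` peaks are found or the residual falls below the detection
#' threshold, followed by a joint refinement of the peaks and a final line
#' refit on the peak-subtracted spectrum. The exponent is reported as a
#' positive number (the negative log-log slope), so smaller values mean a
#' flatter spectrum.
#'
#' @param ps a [welch_psd()] `power_spectrum`.
#' @param channel channel index or name (default 1).
#' @param fit_range frequency range in Hz (default `c(3, 32)`).
#' @param max_n_peaks maximum number of Gaussian peaks (default 5).
#' @param peak_threshold relative detection threshold in residual SDs
#'   (default 2).
#' @param min_peak_height absolute minimum peak height in log10-power units
#'   (default 0.05).
#' @param width_limits Gaussian SD limits in Hz (default `c(0.5, 12)`).
#' @return An object of class `aperiodic_model` with `offset`, `exponent`,
#'   `peaks` (center/height/width matrix), `fit_range` and `fit_error`
#'   (RMSE of the log10 model).
#' @export
fit_aperiodic <- function(ps, channel = 1, fit_range = c(3, 32),
                          max_n_peaks = 5, peak_threshold = 2,
                          min_peak_height = 0.05, width_limits = c(0.5, 12)) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (is.character(channel)) channel <- match(channel, ps$channel_names)
  sel <- ps$freqs >= fit_range[1] & ps$freqs <= fit_range[2]
  if (!any(ps$freqs <= fit_range[1]) || !any(ps$freqs >= fit_range[2]))
    stop("spectrum does not cover the fit range")
  f <- ps$freqs[sel]
  p <- ps$power[channel, sel]
  if (any(p <= 0)) stop("non-positive power inside the fit range")
  logf <- log10(f); logp <- log10(p)

  co <- robust_line(logf, logp)
  resid <- logp - (co[1] + co[2] * logf)
  peaks <- NULL
  for (k in seq_len(max_n_peaks)) {
    i <- which.max(resid)
    h0 <- resid[i]
    if (h0 < max(min_peak_height, peak_threshold * stats::sd(resid))) break
    # initial width from the half-height extent around the maximum
    half <- h0 / 2
    lo <- i; while (lo > 1 && resid[lo - 1] > half) lo <- lo - 1
    hi <- i; while (hi < length(f) && resid[hi + 1] > half) hi <- hi + 1
    w0 <- max(width_limits[1],
              min(width_limits[2], (f[hi] - f[lo]) / 2.355 + 1e-3))
    par0 <- c(f[i], h0, w0)
    obj <- function(par) sum((resid - par[2] *
                                exp(-(f - par[1])^2 / (2 * par[3]^2)))^2)
    fit <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B",
                   lower = c(fit_range[1], min_peak_height / 2, width_limits[1]),
                   upper = c(fit_range[2], 2 * max(resid), width_limits[2])),
      error = function(e) list(par = par0))
    peaks <- rbind(peaks, fit$par)
    resid <- resid - fit$par[2] *
      exp(-(f - fit$par[1])^2 / (2 * fit$par[3]^2))
  }

  if (!is.null(peaks)) {
    # alternate between refitting the line on the peak-subtracted spectrum
    # and jointly refining the peaks against the refit line, so a strong
    # peak cannot tilt the aperiodic slope through the initial line fit
    np <- nrow(peaks)
    for (it in 1:3) {
      co <- robust_line(logf, logp - gauss_sum(f, peaks))
      base_resid <- logp - (co[1] + co[2] * logf)
      obj_all <- function(par) {
        pk <- matrix(par, np, 3)
        sum((base_resid - gauss_sum(f, pk))^2)
      }
      ref <- tryCatch(
        stats::optim(as.vector(peaks), obj_all, method = "L-BFGS-B",
                     lower = rep(c(fit_range[1], min_peak_height / 2,
                                   width_limits[1]), each = np),
                     upper = rep(c(fit_range[2], Inf, width_limits[2]),
                                 each = np)),
        error = function(e) list(par = as.vector(peaks)))
      peaks <- matrix(ref$par, np, 3)
    }
  }

  # final aperiodic refit on the peak-subtracted spectrum
  co <- robust_line(logf, logp - gauss_sum(f, peaks))
  model_log <- co[1] + co[2] * logf + gauss_sum(f, peaks)
  if (!is.null(peaks)) {
    colnames(peaks) <- c("center", "height", "width")
    peaks <- peaks[order(peaks[, 1]), , drop = FALSE]
  } else {
    peaks <- matrix(numeric(0), 0, 3,
                    dimnames = list(NULL, c("center", "height", "width")))
  }
  structure(list(offset = unname(co[1]), exponent = unname(-co[2]),
                 peaks = peaks, fit_range = fit_range,
                 fit_error = sqrt(mean((logp - model_log)^2))),
            class = "aperiodic_model")
}

#' @export
print.aperiodic_model <- function(x, ...) {
  cat(sprintf("<aperiodic_model> offset %.3f, exponent %.3f, %d peak(s), RMSE %.4f\n",
              x$offset, x$exponent, nrow(x$peaks), x$fit_error))
  invisible(x)
}

# log10 aperiodic component at frequencies f (extrapolates below fit range)
aperiodic_log10 <- function(model, f) model$offset - model$exponent * log10(f)

#' Band power, optionally corrected for the aperiodic component
#'
#' Corrected band power is the mean log10 residual (observed minus fitted
#' aperiodic component) over the band's frequency bins — the flattened-
#' spectrum convention, with the aperiodic line extrapolated below the fit
#' range to cover the delta band. Uncorrected mode returns the mean linear
#' power per band.
#'
#' @param ps a `power_spectrum`.
#' @param model an `aperiodic_model` fitted on the same spectrum (only used
#'   when `corrected = TRUE`).
#' @param channel channel index or name.
#' @param bands named list of `c(low, high)` band edges (default
#'   [eeg_bands]).
#' @param corrected logical; remove the aperiodic component (default TRUE).
#' @return Named numeric vector, one value per band, with attribute
#'   `corrected`.
#' @export
corrected_band_power <- function(ps, model = NULL, channel = 1,
                                 bands = eeg_bands, corrected = TRUE) {
  stopifnot(inherits(ps, "power_spectrum"))
  if (is.character(channel)) channel <- match(channel, ps$channel_names)
  if (corrected && !inherits(model, "aperiodic_model"))
    stop("`model` must be an aperiodic_model when corrected = TRUE")
  out <- vapply(bands, function(b) {
    last <- b[2] >= max(vapply(bands, `[`, numeric(1), 2))
    sel <- ps$freqs >= b[1] & (if (last) ps$freqs <= b[2] else ps$freqs < b[2])
    if (!any(sel)) stop("band outside spectrum support")
    p <- ps$power[channel, sel]
    if (corrected) {
      mean(log10(p) - aperiodic_log10(model, ps$freqs[sel]))
    } else {
      mean(p)
    }
  }, numeric(1))
  attr(out, "corrected") <- corrected
  out
}

#' Aperiodic-slope feature
#'
#' Returns the fitted aperiodic exponent with the positive-sign convention:
#' a reduction corresponds to a flatter power spectrum (a shift toward
#' relatively more high-frequency power).
#'
#' @param model an `aperiodic_model`.
#' @return The exponent (dimensionless).
#' @export
slope_feature <- function(model) {
  stopifnot(inherits(model, "aperiodic_model"))
  model$exponent
}
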