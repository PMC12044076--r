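#' @title Synthetic sleep-EEG generation
#' @description Inverse-spectral synthesis of EEG-like signals with an exactly
#'   controlled aperiodic (1/f) exponent and Gaussian oscillatory peaks, plus a
#'   study-level generator that emulates a paired two-condition sleep study
#'   with known ground truth.
#' @name synthetic-data
NULL

# rfft frequency grid for a length-n signal at rate fs (0 .. fs/2)
rfft_freqs <- function(n, fs) seq(0, floor(n / 2)) * fs / n

# Draw one realization of a stationary Gaussian process whose one-sided PSD
# (in power/Hz) is `psd`, given on the rfft grid of length floor(n/2)+1.
# Uses complex-Gaussian Fourier coefficients so the periodogram fluctuates
# like real data. Consumes the current RNG stream.
synth_from_psd <- function(psd, n, fs) {
  nf <- floor(n / 2) + 1L
  stopifnot(length(psd) == nf)
  # E|X_k|^2 = psd_k * fs * n / 2 for interior bins (one-sided density)
  scale <- sqrt(psd * fs * n / 2)
  re <- stats::rnorm(nf) / sqrt(2)
  im <- stats::rnorm(nf) / sqrt(2)
  X <- complex(real = re, imaginary = im) * scale
  X[1] <- 0 + 0i  # zero mean
  if (n %% 2 == 0) X[nf] <- complex(real = re[nf] * sqrt(2), imaginary = 0) * scale[nf]
  full <- c(X, Conj(rev(X[2:(nf - 1L + n %% 2)])))
  Re(stats::fft(full, inverse = TRUE)) / n
}

# Power-law synthesis for any finite exponent (internal; the exported wrapper
# restricts to chi >= 0, the regime meaningful for EEG backgrounds).
synth_powerlaw <- function(exponent, n_samples, fs, seed, normalize = TRUE) {
  if (!is.numeric(exponent) || length(exponent) != 1L || !is.finite(exponent))
    stop("`exponent` must be a single finite number")
  if (n_samples < 64) stop("`n_samples` must be at least 64")
  f <- rfft_freqs(n_samples, fs)
  psd <- c(0, f[-1]^(-exponent))
  x <- with_seed(seed, synth_from_psd(psd, n_samples, fs))
  x <- x - mean(x)
  if (normalize) x <- x / stats::sd(x)
  x
}

#' Synthesize an epoch with a pure 1/f power spectrum
#'
#' Shapes complex-Gaussian Fourier coefficients by `f^(-exponent/2)` and
#' inverse-transforms, giving a zero-mean, unit-variance signal whose
#' log-log PSD slope over the fitting range equals `-exponent` in
#' expectation.
#'
#' @param exponent aperiodic exponent chi >= 0 (0 = white noise).
#' @param n_samples number of samples (>= 64).
#' @param fs sampling rate in Hz.
#' @param seed integer seed; same arguments give bit-identical output.
#' @return Numeric vector of length `n_samples`.
#' @export
synth_aperiodic_epoch <- function(exponent, n_samples, fs, seed) {
  if (!is.numeric(exponent) || length(exponent) != 1L || !is.finite(exponent))
    stop("`exponent` must be a single finite number")
  if (exponent < 0) stop("`exponent` must be >= 0")
  synth_powerlaw(exponent, n_samples, fs, seed)
}

#' Synthesize fractional-Gaussian-noise-like signals by spectral shaping
#'
#' Fractional Gaussian noise with Hurst exponent H has one-sided PSD
#' proportional to `f^(1 - 2H)`; this helper synthesizes such a signal
#' spectrally (power-law exponent `2H - 1`, which is negative for
#' anti-correlated noise). Its DFA scaling exponent is approximately H.
#'
#' @param hurst target Hurst exponent in (0, 1).
#' @inheritParams synth_aperiodic_epoch
#' @return Numeric vector of length `n_samples`, zero mean, unit variance.
#' @export
synth_fgn <- function(hurst, n_samples, fs, seed) {
  stopifnot_scalar(hurst, "hurst")
  if (hurst <= 0 || hurst >= 1) stop("`hurst` must lie in (0, 1)")
  synth_powerlaw(2 * hurst - 1, n_samples, fs, seed)
}

#' Synthesize a narrowband oscillation
#'
#' Band-limited Gaussian noise whose PSD is a Gaussian bump centered at
#' `center` Hz with spectral SD `width` Hz, so > 95% of the power lies
#' within `center +/- 2 * width`. The output RMS equals `amplitude`.
#'
#' @param center peak frequency in Hz, 0 < center < fs/2.
#' @param width spectral width (Gaussian SD) in Hz.
#' @param amplitude RMS amplitude in microvolts; 0 gives a zero vector.
#' @inheritParams synth_aperiodic_epoch
#' @return Numeric vector of length `n_samples`.
#' @export
synth_oscillation <- function(center, width, amplitude, n_samples, fs, seed) {
  stopifnot_scalar(center, "center"); stopifnot_scalar(width, "width")
  stopifnot_scalar(amplitude, "amplitude")
  if (center <= 0 || center >= fs / 2)
    stop("`center` must lie strictly inside (0, fs/2)")
  if (width <= 0 || width >= fs / 2) stop("`width` must lie in (0, fs/2)")
  if (amplitude == 0) return(numeric(n_samples))
  f <- rfft_freqs(n_samples, fs)
  psd <- exp(-(f - center)^2 / (2 * width^2))
  psd[1] <- 0
  x <- with_seed(seed, synth_from_psd(psd, n_samples, fs))
  x <- x - mean(x)
  x / stats::sd(x) * amplitude
}

# effect-injection bump placement: centered in each band, narrow enough
# that the Gaussian tails neither cross band borders nor (for delta) reach
# into the 3-32 Hz aperiodic fit range
band_centers <- c(delta = 1.5, theta = 6, alpha = 10, sigma = 14, beta = 20)
band_widths  <- c(delta = 0.5, theta = 1, alpha = 1, sigma = 1, beta = 1.2)

default_channels <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
                      "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1",
                      "O2", "Oz")

#' Configuration for a synthetic paired sleep study
#'
#' Defines the shape and physiology of the generated study: a paired
#' caffeine/placebo design over two age groups, 20-channel 10-20 montage,
#' 20-s epochs, NREM and REM baselines with distinct aperiodic exponents
#' and oscillatory peaks, and injectable condition effects (aperiodic
#' flattening `d_chi`, per-band peak-height changes in log10 power).
#'
#' @param n_subjects number of subjects (paired design: 2 nights each).
#' @param age_group_split named counts `c(young = ..., middle = ...)`; must
#'   sum to `n_subjects`.
#' @param channel_names 10-20 montage labels.
#' @param fs sampling rate (Hz).
#' @param epoch_len epoch length (s); `fs * epoch_len` must be integral.
#' @param n_nrem,n_rem epochs per recording by stage (roughly 3:1).
#' @param baseline named list per stage with `chi` (aperiodic exponent),
#'   `offset` (log10 microvolts^2/Hz at 1 Hz) and `peaks` (matrix with
#'   columns center, height, width).
#' @param condition_effects list with `d_chi` (caffeine flattening, positive
#'   = flatter) and `band_height_delta` (named per band, log10 power added
#'   under caffeine).
#' @param subject_sd list of between-subject SDs: `chi`, `offset`, `effect`
#'   (SD of the per-subject condition effect multiplier around 1).
#' @param age_effect named multipliers `c(young = ..., middle = ...)` scaling
#'   all condition effects per age group.
#' @param seed integer seed; the whole study is a pure function of the config.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_subjects = 40,
                         age_group_split = c(young = 22, middle = 18),
                         channel_names = default_channels,
                         fs = 256, epoch_len = 20,
                         n_nrem = 300, n_rem = 100,
                         baseline = list(
                           NREM = list(
                             chi = 2.0, offset = 1.2,
                             peaks = rbind(c(1.5, 0.6, 0.6), c(13.5, 0.4, 1.0))),
                           REM = list(
                             chi = 1.5, offset = 0.9,
                             peaks = rbind(c(1.5, 0.25, 0.6), c(6.0, 0.35, 1.5)))),
                         condition_effects = list(
                           d_chi = 0.3,
                           band_height_delta = c(delta = -0.2, theta = -0.15,
                                                 alpha = -0.1, sigma = 0,
                                                 beta = 0.15)),
                         subject_sd = list(chi = 0.15, offset = 0.2,
                                           effect = 0.1),
                         age_effect = c(young = 1, middle = 1),
                         seed = 1) {
  if (fs <= 0) stop("`fs` must be positive")
  n_samp <- fs * epoch_len
  if (abs(n_samp - round(n_samp)) > 1e-9)
    stop("`fs * epoch_len` must be an integer sample count")
  if (n_nrem < 1 || n_rem < 1) stop("epoch counts must be >= 1")
  if (sum(age_group_split) != n_subjects)
    stop("`age_group_split` must sum to `n_subjects`")
  for (st in names(baseline)) {
    b <- baseline[[st]]
    if (b$chi < 0) stop("baseline chi must be >= 0")
    if (!is.null(b$peaks) && nrow(b$peaks) > 0) {
      if (any(b$peaks[, 3] <= 0 | b$peaks[, 3] >= fs / 2))
        stop("peak widths must lie in (0, fs/2)")
      if (any(b$peaks[, 1] <= 0 | b$peaks[, 1] >= fs / 2))
        stop("peak centers must lie in (0, fs/2)")
    }
  }
  structure(
    list(n_subjects = n_subjects, age_group_split = age_group_split,
         channel_names = channel_names, fs = fs, epoch_len = epoch_len,
         n_nrem = n_nrem, n_rem = n_rem, baseline = baseline,
         condition_effects = condition_effects, subject_sd = subject_sd,
         age_effect = age_effect, seed = seed),
    class = "study_config")
}

# Target log10 one-sided PSD on grid f for given aperiodic + peak parameters.
target_log_psd <- function(f, chi, offset, peaks) {
  lp <- rep(offset, length(f))
  pos <- f > 0
  lp[pos] <- offset - chi * log10(f[pos])
  if (!is.null(peaks) && nrow(peaks) > 0) {
    for (i in seq_len(nrow(peaks)))
      lp <- lp + peaks[i, 2] * exp(-(f - peaks[i, 1])^2 / (2 * peaks[i, 3]^2))
  }
  lp[1] <- -Inf  # DC removed
  lp
}

#' Generate a full synthetic paired sleep study
#'
#' Produces one caffeine and one placebo [epoched_recording()] per subject,
#' with NREM and REM epochs, and a ground-truth table of the true aperiodic
#' parameters per subject/condition/stage. Caffeine recordings are built
#' with the aperiodic exponent reduced by `d_chi` (spectral flattening) and
#' per-band Gaussian height changes applied, scaled by the subject's age
#' group and a per-subject effect multiplier.
#'
#' @param config a [study_config()].
#' @return A list with `recordings` (list of `epoched_recording`, one per
#'   subject x condition) and `ground_truth` (tibble: subject_id, age_group,
#'   condition, stage, chi, offset).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  n_samp <- as.integer(round(cfg$fs * cfg$epoch_len))
  f <- rfft_freqs(n_samp, cfg$fs)
  age <- rep(names(cfg$age_group_split), cfg$age_group_split)
  subjects <- sprintf("s%02d", seq_len(cfg$n_subjects))
  stages <- c(rep("NREM", cfg$n_nrem), rep("REM", cfg$n_rem))

  recs <- list()
  gt <- list()
  with_seed(cfg$seed, {
    for (i in seq_len(cfg$n_subjects)) {
      # subject-level random offsets, shared by both nights
      chi_off <- stats::rnorm(1, 0, cfg$subject_sd$chi)
      off_off <- stats::rnorm(1, 0, cfg$subject_sd$offset)
      eff_mult <- max(0, stats::rnorm(1, 1, cfg$subject_sd$effect)) *
        cfg$age_effect[[age[i]]]
      for (cond in c("placebo", "caffeine")) {
        d_chi <- if (cond == "caffeine") cfg$condition_effects$d_chi * eff_mult else 0
        bh <- if (cond == "caffeine")
          cfg$condition_effects$band_height_delta * eff_mult
        else
          stats::setNames(rep(0, 5), names(band_centers))
        # per-stage target spectra
        logpsd <- list()
        for (st in c("NREM", "REM")) {
          b <- cfg$baseline[[st]]
          chi <- max(0, b$chi + chi_off - d_chi)
          peaks <- b$peaks
          extra <- do.call(rbind, lapply(names(bh)[bh != 0], function(bn)
            c(band_centers[[bn]], bh[[bn]], band_widths[[bn]])))
          if (!is.null(extra)) peaks <- rbind(peaks, extra)
          logpsd[[st]] <- target_log_psd(f, chi, b$offset + off_off, peaks)
          gt[[length(gt) + 1L]] <- tibble::tibble(
            subject_id = subjects[i], age_group = age[i], condition = cond,
            stage = st, chi = chi, offset = b$offset + off_off)
        }
        arr <- array(0, dim = c(length(stages), length(cfg$channel_names), n_samp))
        for (e in seq_along(stages)) {
          psd <- 10^logpsd[[stages[e]]]
          psd[1] <- 0
          for (ch in seq_along(cfg$channel_names))
            arr[e, ch, ] <- synth_from_psd(psd, n_samp, cfg$fs)
        }
        recs[[paste(subjects[i], cond, sep = "_")]] <- epoched_recording(
          arr, stages, cfg$fs, cfg$channel_names, subjects[i], cond, age[i],
          cfg$epoch_len)
      }
    }
  })
  list(recordings = recs, ground_truth = dplyr::bind_rows(gt))
}
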