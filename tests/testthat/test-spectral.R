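test_that("Welch PSD satisfies Parseval and locates sinusoid power", {
  fs <- 256
  t <- seq_len(fs * 20) / fs
  ps <- welch_psd(sin(2 * pi * 10 * t), fs)
  expect_equal(diff(ps$freqs)[1], 0.25)
  expect_equal(ps$freqs[which.max(ps$power[1, ])], 10)
  df <- diff(ps$freqs)[1]
  expect_equal(sum(ps$power) * df, 0.5, tolerance = 0.05)

  set.seed(9)
  x <- rnorm(fs * 20, sd = 3)
  psn <- welch_psd(x, fs)
  expect_equal(sum(psn$power) * df, var(x), tolerance = 0.1 * var(x))
  expect_error(welch_psd(rnorm(100), fs), "shorter than one Welch window")
})

test_that("an exact power law is fit with no peaks and exact parameters", {
  fs <- 256
  ps <- welch_psd(rnorm(fs * 20), fs)
  ps$power <- matrix(10^1.2 * pmax(ps$freqs, 1e-3)^(-2), nrow = 1)
  m <- fit_aperiodic(ps)
  expect_equal(m$exponent, 2, tolerance = 0.02)
  expect_equal(m$offset, 1.2, tolerance = 0.02)
  expect_identical(nrow(m$peaks), 0L)
  expect_lt(m$fit_error, 1e-6)
  expect_equal(slope_feature(m), m$exponent)
})

test_that("a Gaussian bump is separated from the power law", {
  est <- t(vapply(1:20, function(s) {
    f <- sleepcrit:::rfft_freqs(5120, 256)
    lp <- sleepcrit:::target_log_psd(f, 2, 1.2, rbind(c(10, 0.5, 1.5)))
    psd <- 10^lp; psd[1] <- 0
    x <- sleepcrit:::with_seed(s, sleepcrit:::synth_from_psd(psd, 5120, 256))
    m <- fit_aperiodic(welch_psd(x, 256))
    c(m$exponent, m$peaks[which.max(m$peaks[, "height"]), "center"])
  }, numeric(2)))
  expect_lt(abs(mean(est[, 1]) - 2), 0.1)
  expect_lt(abs(mean(est[, 2]) - 10), 0.5)
})

test_that("the peak count is capped at five", {
  f <- sleepcrit:::rfft_freqs(5120, 256)
  pk <- cbind(seq(4, 30, length.out = 8), 0.8, 0.8)
  lp <- sleepcrit:::target_log_psd(f, 1, 1, pk)
  psd <- 10^lp; psd[1] <- 0
  for (s in 1:5) {
    x <- sleepcrit:::with_seed(s, sleepcrit:::synth_from_psd(psd, 5120, 256))
    m <- fit_aperiodic(welch_psd(x, 256), peak_threshold = 0.5)
    expect_lte(nrow(m$peaks), 5L)
  }
})

test_that("adding one oscillation shifts the recovered exponent by < 0.1", {
  est <- vapply(1:20, function(s) {
    x0 <- synth_aperiodic_epoch(1.5, 5120, 256, s)
    x1 <- x0 + synth_oscillation(10, 1, 0.5, 5120, 256, s + 1000)
    fit_aperiodic(welch_psd(x1, 256))$exponent -
      fit_aperiodic(welch_psd(x0, 256))$exponent
  }, numeric(1))
  expect_lt(abs(mean(est)), 0.1)
})

test_that("corrected band power is the log residual, with delta extrapolated", {
  fs <- 256
  ps <- welch_psd(rnorm(fs * 20), fs)
  # spectrum exactly equal to its aperiodic model -> all residuals zero
  ps$power <- matrix(10^1.0 * pmax(ps$freqs, 1e-3)^(-1.5), nrow = 1)
  m <- fit_aperiodic(ps)
  bp <- corrected_band_power(ps, m)
  expect_identical(names(bp), c("delta", "theta", "alpha", "sigma", "beta"))
  expect_true(all(abs(bp) < 0.01))

  # alpha bump on top: alpha residual positive, others comparatively flat
  f <- ps$freqs
  ps2 <- ps
  ps2$power <- matrix(10^(1.0 - 1.5 * log10(pmax(f, 1e-3)) +
                            0.5 * exp(-(f - 10)^2 / (2 * 1^2))), nrow = 1)
  m2 <- fit_aperiodic(ps2)
  bp2 <- corrected_band_power(ps2, m2)
  expect_gt(bp2[["alpha"]], 0.1)
  expect_true(all(abs(bp2[c("delta", "theta", "sigma", "beta")]) <
                    0.1 * bp2[["alpha"]]))

  # uncorrected mode on a flat spectrum returns the density itself
  ps3 <- ps
  ps3$power <- matrix(rep(2.5, length(f)), nrow = 1)
  bp3 <- corrected_band_power(ps3, corrected = FALSE)
  expect_true(all(abs(bp3 - 2.5) < 1e-12))
})

test_that("the slope feature increases monotonically with the true exponent", {
  est <- vapply(c(0.5, 1, 1.5, 2), function(chi) {
    mean(vapply(1:5, function(s)
      fit_aperiodic(welch_psd(synth_aperiodic_epoch(chi, 5120, 256, s),
                              256))$exponent, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})
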