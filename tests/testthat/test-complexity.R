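test_that("sample entropy handles analytic and degenerate cases", {
  # alternating +-1: every length-2 match extends, so A = B and SampEn = 0
  alt <- rep(c(1, -1), 32)
  ab <- oracle_sampen_counts(alt, 2, 0.2)
  expect_identical(ab[["A"]], ab[["B"]])
  expect_identical(sample_entropy(alt), 0)
  expect_error(sample_entropy(rep(1, 64)), "zero variance")
  expect_error(sample_entropy(c(1, 2, 3), m = 2), "length")
  # A = 0 sentinel: strictly increasing ramp with tiny tolerance
  expect_identical(sample_entropy(2^(1:24), r = 1e-6), Inf)
})

test_that("all metrics match brute-force oracles on random inputs", {
  set.seed(101)
  for (i in 1:20) {
    n <- sample(50:512, 1)
    x <- rnorm(n)
    expect_identical(sample_entropy(x), oracle_sampen(x))
    expect_identical(lempel_ziv(x), oracle_lzc(x))
    expect_equal(permutation_entropy(x), oracle_permen(x), tolerance = 1e-12)
  }
  # spectral metrics against their oracles on a fixed-seed PSD
  x <- rnorm(256 * 20)
  ps <- welch_psd(x, 256)
  sel <- ps$freqs >= 0.5 & ps$freqs <= 32
  expect_equal(spectral_entropy(ps), oracle_specen(ps$power[1, sel]),
               tolerance = 1e-12)
  expect_identical(spectral_sample_entropy(ps),
                   oracle_sampen(ps$power[1, sel]))
})

test_that("LZ76 parsing matches the substring oracle exhaustively", {
  # every binary string of length 8, plus random longer strings
  for (v in 0:255) {
    bits <- as.integer(intToBits(v)[1:8])
    expect_identical(sleepcrit:::.lz76_count(bits), oracle_lz76(bits))
  }
  set.seed(7)
  for (i in 1:25) {
    bits <- sample(0:1, sample(9:32, 1), replace = TRUE)
    expect_identical(sleepcrit:::.lz76_count(bits), oracle_lz76(bits))
  }
  bits <- sample(0:1, 1024, replace = TRUE)
  expect_identical(sleepcrit:::.lz76_count(bits), oracle_lz76(bits))
})

test_that("LZc ranks periodic below random signals", {
  set.seed(3)
  expect_lt(lempel_ziv(sin(2 * pi * (1:4096) / 64)), lempel_ziv(rnorm(4096)))
  expect_error(lempel_ziv(rep(2, 100)), "zero variance")
})

test_that("spectral entropy spans its [0, 1] range at the extremes", {
  fs <- 256
  ps <- welch_psd(rnorm(fs * 20), fs)
  nb <- sum(ps$freqs >= 0.5 & ps$freqs <= 32)
  one_bin <- ps; one_bin$power <- matrix(0, 1, length(ps$freqs))
  one_bin$power[1, which(ps$freqs == 10)] <- 5
  expect_equal(spectral_entropy(one_bin), 0)
  flat <- ps; flat$power <- matrix(1, 1, length(ps$freqs))
  expect_equal(spectral_entropy(flat), 1)
  # alternating two-level PSD has SpecSampEn 0; a flat one is degenerate
  twolevel <- ps
  twolevel$power <- matrix(rep(c(1, 3), length.out = length(ps$freqs)), 1)
  expect_identical(spectral_sample_entropy(twolevel), 0)
  expect_error(spectral_sample_entropy(flat), "zero variance")
})

test_that("permutation entropy handles ramps and tiny cases", {
  expect_equal(permutation_entropy(1:50), 0)
  # length-4 toy, order 3: patterns of (1,2,3) and (2,3,1)-ranked triples
  x <- c(1, 2, 3, 1)
  expect_equal(permutation_entropy(x, order = 3), oracle_permen(x, 3))
  expect_error(permutation_entropy(1:3, order = 3), "too short")
})

test_that("metrics are invariant to positive affine rescaling", {
  set.seed(11)
  x <- rnorm(400)
  y <- 3.7 * x + 12
  expect_equal(sample_entropy(y), sample_entropy(x))
  expect_identical(lempel_ziv(y), lempel_ziv(x))
  expect_equal(permutation_entropy(y), permutation_entropy(x))
})

test_that("SampEn and LZc increase with the noise share of a noisy sinusoid", {
  # constant-variance interpolation between a pure sinusoid and white noise
  t <- (1:2048) / 256
  s <- sin(2 * pi * 10 * t) * sqrt(2)
  set.seed(5)
  e <- rnorm(2048)
  w <- seq(0, 1, length.out = 11)
  mix <- function(wi) sqrt(1 - wi) * s + sqrt(wi) * e
  se <- vapply(w, function(wi) sample_entropy(mix(wi)), numeric(1))
  lz <- vapply(w, function(wi) lempel_ziv(mix(wi)), numeric(1))
  expect_gt(cor(w, se, method = "spearman"), 0.9)
  expect_gt(cor(w, lz, method = "spearman"), 0.9)
})
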