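# Independent brute-force oracles, written against the definitions only.
# These never share code paths with the package implementation.

# SampEn match counts by direct double loop over template pairs,
# Chebyshev distance, self-matches excluded (i < j), templates restricted
# to the first n - m starting positions so A and B are comparable.
oracle_sampen_counts <- function(x, m, r) {
  n <- length(x)
  tol <- r * sd(x)
  A <- 0; B <- 0
  for (i in 1:(n - m - 1)) {
    for (j in (i + 1):(n - m)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= tol) {
        B <- B + 1
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= tol) A <- A + 1
      }
    }
  }
  c(A = A, B = B)
}

oracle_sampen <- function(x, m = 2, r = 0.2) {
  ab <- oracle_sampen_counts(x, m, r)
  if (ab["A"] == 0 || ab["B"] == 0) return(Inf)
  -log(ab[["A"]] / ab[["B"]])
}

# LZ76 phrase count by the substring definition: each new phrase is the
# shortest extension not contained in the preceding text (history plus the
# phrase minus its last symbol); a trailing reproducible phrase still counts.
oracle_lz76 <- function(bits) {
  s <- paste(bits, collapse = "")
  n <- nchar(s)
  c_n <- 0L
  pos <- 1L
  while (pos <= n) {
    k <- 1L
    while (pos + k - 1L < n &&
           grepl(substr(s, pos, pos + k - 1L),
                 substr(s, 1, pos + k - 2L), fixed = TRUE)) {
      k <- k + 1L
    }
    c_n <- c_n + 1L
    pos <- pos + k
  }
  c_n
}

oracle_lzc <- function(x) {
  bits <- as.integer(x > median(x))
  oracle_lz76(bits) * log2(length(x)) / length(x)
}

# Shannon spectral entropy straight from the definition
oracle_specen <- function(p) {
  pr <- p / sum(p)
  pr <- pr[pr > 0]
  -sum(pr * log(pr)) / log(length(p))
}

# Permutation entropy by explicit enumeration of all order! rank patterns
oracle_permen <- function(x, order = 3, delay = 1) {
  n_pat <- length(x) - (order - 1) * delay
  perms <- as.matrix(expand.grid(rep(list(1:order), order)))
  perms <- perms[apply(perms, 1, function(r) length(unique(r)) == order), ]
  counts <- numeric(nrow(perms))
  for (i in seq_len(n_pat)) {
    v <- x[i + (0:(order - 1)) * delay]
    rk <- rank(v, ties.method = "first")
    hit <- which(apply(perms, 1, function(r) all(r == rk)))
    counts[hit] <- counts[hit] + 1
  }
  pr <- counts[counts > 0] / n_pat
  -sum(pr * log(pr)) / log(factorial(order))
}

# Shared tiny-study config for feature/pipeline tests (fast rate, Nyquist
# still above the 32 Hz fit edge)
tiny_study <- function(n_subjects = 4, n_nrem = 4, n_rem = 2, seed = 11,
                       channels = c("Fz", "Cz", "Pz"), fs = 80,
                       condition_effects = NULL, age_split = NULL) {
  if (is.null(age_split)) {
    ny <- ceiling(n_subjects / 2)
    age_split <- c(young = ny, middle = n_subjects - ny)
  }
  args <- list(n_subjects = n_subjects, age_group_split = age_split,
               channel_names = channels, fs = fs, n_nrem = n_nrem,
               n_rem = n_rem, seed = seed)
  if (!is.null(condition_effects)) args$condition_effects <- condition_effects
  do.call(study_config, args)
}

null_effects <- list(d_chi = 0, band_height_delta = c(delta = 0, theta = 0,
                                                      alpha = 0, sigma = 0,
                                                      beta = 0))
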