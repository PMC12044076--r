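study_tables <- function(...) {
  st <- generate_study(tiny_study(...))
  recs <- lapply(st$recordings, bandpass)
  epoch_tab <- dplyr::bind_rows(lapply(recs, extract_features, stage = "NREM"))
  list(epoch = epoch_tab, subject = average_by_subject(epoch_tab))
}

test_that("epoch-level extraction yields the canonical table shape", {
  tabs <- study_tables(n_subjects = 2, n_nrem = 3, n_rem = 1, seed = 31)
  et <- tabs$epoch
  expect_true(all(canonical_features %in% names(et)))
  expect_identical(nrow(et), 2L * 2L * 3L * 3L)  # subj x cond x epoch x chan
  expect_false(any(duplicated(
    et[, c("subject_id", "condition", "channel", "epoch_index")])))
  # determinism
  et2 <- study_tables(n_subjects = 2, n_nrem = 3, n_rem = 1, seed = 31)$epoch
  expect_identical(et, et2)
})

test_that("degenerate epochs are flagged as cells, never as failures", {
  fs <- 80
  n <- fs * 20
  set.seed(8)
  arr <- array(rnorm(2 * 1 * n), c(2, 1, n))
  arr[2, 1, ] <- 5  # zero-variance epoch: every metric degenerates
  rec <- epoched_recording(arr, c("NREM", "NREM"), fs, "Cz")
  et <- extract_features(rec, "NREM")
  bad <- et[et$epoch_index == 2, ]
  expect_true(is.na(bad$sampen) && is.na(bad$lzc) && is.na(bad$dfa_alpha))
  good <- et[et$epoch_index == 1, ]
  expect_true(all(is.finite(unlist(good[, canonical_features]))))
})

test_that("subject averaging is the mean over valid epochs only", {
  tabs <- study_tables(n_subjects = 2, n_nrem = 4, n_rem = 1, seed = 32)
  et <- tabs$epoch
  cell <- et[et$subject_id == "s01" & et$condition == "placebo" &
               et$channel == "Cz", ]
  avg <- tabs$subject
  a <- avg[avg$subject_id == "s01" & avg$condition == "placebo" &
             avg$channel == "Cz", ]
  expect_equal(a$sampen, mean(cell$sampen))
  # flag one epoch: the average must use the remaining three
  et2 <- et
  i <- which(et2$subject_id == "s01" & et2$condition == "placebo" &
               et2$channel == "Cz")
  et2$sampen[i[1]] <- Inf
  a2 <- average_by_subject(et2)
  expect_equal(
    a2$sampen[a2$subject_id == "s01" & a2$condition == "placebo" &
                a2$channel == "Cz"],
    mean(et$sampen[i[-1]]))
  # a cell with no valid epochs is an error
  et3 <- et
  et3$sampen[i] <- NA
  expect_error(average_by_subject(et3), "zero valid epochs")
})

test_that("the z-transform is per subject, shift-invariant and leakage-free", {
  tabs <- study_tables(n_subjects = 3, n_nrem = 3, n_rem = 1, seed = 33)
  z <- z_transform(tabs$subject, tabs$epoch)
  expect_true(isTRUE(attr(z, "zscored")))

  # adding a constant to one subject's raw values leaves its z-scores alone
  et_shift <- tabs$epoch
  st_shift <- tabs$subject
  sel_e <- et_shift$subject_id == "s01"
  sel_s <- st_shift$subject_id == "s01"
  et_shift$lzc[sel_e] <- et_shift$lzc[sel_e] + 5
  st_shift$lzc[sel_s] <- st_shift$lzc[sel_s] + 5
  z2 <- z_transform(st_shift, et_shift)
  expect_equal(z2$lzc[z2$subject_id == "s01"], z$lzc[z$subject_id == "s01"])

  # perturbing subject s01 never changes subject s02's z-scores
  et_pert <- tabs$epoch
  et_pert$sampen[et_pert$subject_id == "s01"] <-
    et_pert$sampen[et_pert$subject_id == "s01"] * 3 + 1
  z3 <- z_transform(tabs$subject, et_pert)
  expect_identical(z3$sampen[z3$subject_id == "s02"],
                   z$sampen[z$subject_id == "s02"])

  # monotone transform preserves within-subject channel ordering
  s2 <- z[z$subject_id == "s02" & z$condition == "placebo", ]
  r2 <- tabs$subject[tabs$subject$condition == "placebo" &
                       tabs$subject$subject_id == "s02", ]
  expect_identical(order(s2$specen), order(r2$specen))

  expect_error(z_transform(tabs$subject, dplyr::mutate(tabs$epoch, lzc = 1)),
               "zero or undefined SD")
})

test_that("z-scored subject means of standard-normal features are near zero", {
  # epoch-level values ~ N(0,1): transformed subject means within the CLT band
  set.seed(44)
  n_ep <- 60
  et <- tibble::tibble(
    subject_id = "s01", condition = rep(c("caffeine", "placebo"), each = n_ep / 2),
    age_group = "young", stage = "NREM", channel = "Cz",
    epoch_index = seq_len(n_ep))
  for (f in canonical_features) et[[f]] <- rnorm(n_ep)
  st <- average_by_subject(et)
  z <- z_transform(st, et)
  vals <- unlist(z[, canonical_features])
  expect_true(all(abs(vals) < 3 / sqrt(n_ep / 2)))
})

test_that("the feature matrix has one column per (feature, channel) pair", {
  tabs <- study_tables(n_subjects = 2, n_nrem = 2, n_rem = 1, seed = 35)
  fm <- feature_matrix(z_transform(tabs$subject, tabs$epoch))
  expect_identical(dim(fm$x), c(4L, 33L))  # 2x2 samples, 11 x 3 columns
  expect_identical(levels(fm$y), c("placebo", "caffeine"))
  # spot check one cell against the long table
  z <- z_transform(tabs$subject, tabs$epoch)
  v <- z$lzc[z$subject_id == "s02" & z$condition == "caffeine" &
               z$channel == "Pz"]
  i <- which(fm$meta$subject_id == "s02" & fm$meta$condition == "caffeine")
  expect_equal(fm$x[i, "lzc.Pz"], v, ignore_attr = TRUE)
})
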