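#' Standard 10-20 head-schematic coordinates
#'
#' 2-D coordinates in a unit head circle (vertex Cz at the origin, nose
#' up), for the 20-channel montage used throughout the package.
#' @export
channel_layout <- function() {
  tibble::tribble(
    ~channel, ~x, ~y,
    "Fp1", -0.31,  0.95, "Fp2",  0.31,  0.95,
    "F7",  -0.81,  0.59, "F3",  -0.55,  0.48, "Fz", 0,  0.5,
    "F4",   0.55,  0.48, "F8",   0.81,  0.59,
    "T3",  -1.00,  0.00, "C3",  -0.50,  0.00, "Cz", 0,  0.0,
    "C4",   0.50,  0.00, "T4",   1.00,  0.00,
    "T5",  -0.81, -0.59, "P3",  -0.55, -0.48, "Pz", 0, -0.5,
    "P4",   0.55, -0.48, "T6",   0.81, -0.59,
    "O1",  -0.31, -0.95, "O2",   0.31, -0.95, "Oz", 0, -1.0)
}

#' Attach head-schematic coordinates to a per-channel table
#'
#' Numeric backing for topographic maps: each known 10-20 label is mapped
#' to its 2-D layout coordinate; unknown labels are kept and flagged
#' (`known = FALSE`, NA coordinates) rather than dropped.
#'
#' @param per_channel_table tibble with a `channel` column.
#' @return The table with `x`, `y` and `known` columns appended.
#' @export
report_topography_values <- function(per_channel_table) {
  lay <- channel_layout()
  idx <- match(per_channel_table$channel, lay$channel)
  out <- per_channel_table
  out$x <- lay$x[idx]
  out$y <- lay$y[idx]
  out$known <- !is.na(idx)
  out
}

#' Pipeline configuration
#'
#' @param study a [study_config()] for synthetic mode, or NULL.
#' @param metadata in real-data mode, a data frame with columns
#'   subject_id, condition, age_group, edf_path, hypnogram_path.
#' @param stages sleep stages to analyze.
#' @param artifact_threshold amplitude rejection threshold (microvolts).
#' @param band band-pass edges in Hz.
#' @param n_perm permutations for the paired pseudo-T tests.
#' @param decode_model single-feature classifier (`"lda"` or `"svm_rbf"`)
#'   or NULL to skip decoding.
#' @param decode_n_perm label permutations for decoding (0 = accuracies
#'   only).
#' @param rf_repeats random-forest repetitions (0 skips the RF stage).
#' @param features feature columns to test/decode.
#' @param out_dir output directory for TSVs and the manifest, or NULL to
#'   return results only.
#' @param seed master seed for all stochastic stages.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(study = NULL, metadata = NULL,
                            stages = c("NREM", "REM"),
                            artifact_threshold = 300, band = c(0.5, 32),
                            n_perm = 1000, decode_model = "lda",
                            decode_n_perm = 0, rf_repeats = 0,
                            features = canonical_features,
                            out_dir = NULL, seed = 1) {
  if (is.null(study) && is.null(metadata))
    stop("provide either a synthetic `study` config or real-data `metadata`")
  structure(list(study = study, metadata = metadata, stages = stages,
                 artifact_threshold = artifact_threshold, band = band,
                 n_perm = n_perm, decode_model = decode_model,
                 decode_n_perm = decode_n_perm, rf_repeats = rf_repeats,
                 features = features, out_dir = out_dir, seed = seed),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Loads or generates the recordings, band-pass filters and
#' artifact-rejects them, extracts per-epoch features, averages within
#' subject and z-transforms, then runs the paired permutation pseudo-T
#' tests (and optionally single-feature decoding and the multi-feature
#' random forest) per stage and feature. When `out_dir` is set, all result
#' tables are written as TSV together with a manifest (config hash, seed,
#' package version); identical configs reproduce byte-identical outputs.
#'
#' @param config a [pipeline_config()].
#' @return List with per-stage elements: `features_epoch`,
#'   `features_subject` (z-scored), `stats` (per feature x channel),
#'   `decoding`, `rf` and the `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage_try <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))

  recs <- stage_try("load", {
    if (!is.null(config$study)) {
      generate_study(config$study)$recordings
    } else {
      md <- config$metadata
      lapply(seq_len(nrow(md)), function(i)
        read_recording(md$edf_path[i], md$hypnogram_path[i],
                       md$subject_id[i], md$condition[i], md$age_group[i]))
    }
  })
  recs <- stage_try("preprocess", lapply(recs, function(r)
    reject_artifact_epochs(bandpass(r, config$band[1], config$band[2]),
                           config$artifact_threshold)))

  manifest <- tibble::tibble(
    key = c("config_hash", "seed", "package", "version"),
    value = c(rlang::hash(config), as.character(config$seed), "sleepcrit",
              as.character(utils::packageVersion("sleepcrit"))))
  out <- list(manifest = manifest)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"))
  }

  for (stage in config$stages) {
    epoch_tab <- stage_try("features", dplyr::bind_rows(
      lapply(recs, extract_features, stage = stage)))
    subj_tab <- stage_try("average", average_by_subject(epoch_tab))
    z_tab <- stage_try("ztransform", z_transform(subj_tab, epoch_tab))

    stats_tab <- stage_try("stats", dplyr::bind_rows(lapply(
      config$features, function(f) {
        a <- feature_matrix_by_condition(z_tab, f, "caffeine")
        b <- feature_matrix_by_condition(z_tab, f, "placebo")
        res <- paired_perm_pseudo_t(a, b, n_perm = config$n_perm,
                                    seed = derive_seed(config$seed, 1))
        tab <- dplyr::mutate(res$table,
                             sig05 = .data$p_corrected < 0.05,
                             sig01 = .data$p_corrected < 0.01)
        dplyr::mutate(tab, feature = f, .before = 1)
      })))

    dec_tab <- NULL
    if (!is.null(config$decode_model)) {
      dec_tab <- stage_try("decode", dplyr::bind_rows(lapply(
        config$features, function(f) {
          a <- feature_matrix_by_condition(z_tab, f, "caffeine")
          b <- feature_matrix_by_condition(z_tab, f, "placebo")
          x <- rbind(a, b)
          y <- factor(rep(c("caffeine", "placebo"), c(nrow(a), nrow(b))))
          res <- decode_single_feature(
            x, y, groups = c(rownames(a), rownames(b)),
            model = config$decode_model,
            k = min(10, length(unique(rownames(a)))),
            n_perm = config$decode_n_perm,
            seed = derive_seed(config$seed, 2))
          dplyr::mutate(res$table, feature = f, .before = 1)
        })))
    }

    rf_res <- NULL
    if (config$rf_repeats > 0) {
      rf_res <- stage_try("rf", {
        fm <- feature_matrix(z_tab, config$features)
        rf_multifeature(fm$x, fm$y, fm$groups, n_repeats = config$rf_repeats,
                        n_holdout = min(5, length(unique(fm$groups)) - 2),
                        inner_k = min(7, length(unique(fm$groups)) - 5),
                        seed = derive_seed(config$seed, 3))
      })
    }

    out[[stage]] <- list(features_epoch = epoch_tab, features_subject = z_tab,
                         stats = stats_tab, decoding = dec_tab, rf = rf_res)
    if (!is.null(config$out_dir)) {
      write_tsv(epoch_tab,
                file.path(config$out_dir, sprintf("features_epoch_%s.tsv", stage)))
      write_tsv(z_tab,
                file.path(config$out_dir, sprintf("features_subject_%s.tsv", stage)))
      write_tsv(stats_tab, file.path(config$out_dir, sprintf("stats_%s.tsv", stage)))
      if (!is.null(dec_tab))
        write_tsv(dec_tab, file.path(config$out_dir, sprintf("decode_%s.tsv", stage)))
      if (!is.null(rf_res))
        write_tsv(rf_res$importance,
                  file.path(config$out_dir, sprintf("importance_%s.tsv", stage)))
    }
  }
  out
}
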