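# Pipeline plumbing: configuration, provenance manifests, and the
# simulate / screen entry points that tie the stages into a reproducible run.
# A thin command-line wrapper over these functions ships in inst/cli/.

#' Pipeline configuration
#'
#' Bundles every tunable of a simulate + screen run. All randomness flows from
#' the single `seed`; per-subject streams are derived by counter, so a rerun
#' with the same configuration is byte-identical.
#'
#' @param n_subjects cohort size (default 51).
#' @param seed root RNG seed.
#' @param height,width rendered patch size in pixels (default 64).
#' @param window_side uniform-region window side (default 16).
#' @param block_side block-aggregation side for the coarsened re-analysis
#'   (default 2).
#' @param outlier_k SD multiplier for population outlier exclusion (default 3).
#' @param limit_green,limit_blue discrimination limits, 0-255 intensity
#'   (defaults 212 and 190).
#' @param clinical_threshold TsB defining the condition, umol/L (default 205).
#' @param qc a [qc_thresholds()].
#' @param tsb a [tsb_profile()].
#' @param effects a [channel_effect_model()]; `NULL` means the calibrated
#'   default for `tsb` and `window_side`.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 51, seed = 1L, height = 64, width = 64,
                            window_side = 16, block_side = 2, outlier_k = 3,
                            limit_green = 212, limit_blue = 190,
                            clinical_threshold = 205,
                            qc = qc_thresholds(), tsb = tsb_profile(),
                            effects = NULL) {
  if (clinical_threshold <= 0)
    stopf("pipeline_config: clinical_threshold must be > 0")
  for (L in c(limit_green, limit_blue))
    if (L < 0 || L > 255) stopf("pipeline_config: limits must lie in [0, 255]")
  if (is.null(effects))
    effects <- default_effect_model(tsb = tsb, region_pixels = window_side^2)
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 height = height, width = width, window_side = window_side,
                 block_side = block_side, outlier_k = outlier_k,
                 limit_green = limit_green, limit_blue = limit_blue,
                 clinical_threshold = clinical_threshold, qc = qc,
                 tsb = tsb, effects = effects),
            class = "pipeline_config")
}

#' Read a pipeline configuration from JSON or YAML
#'
#' Recognised top-level keys are the arguments of [pipeline_config()]
#' (scalar ones); unknown keys raise an error.
#'
#' @param path `.json`, `.yaml` or `.yml` file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stopf("read_pipeline_config: YAML configs require the 'yaml' package")
    yaml::read_yaml(path)
  } else stopf("read_pipeline_config: unsupported config format '%s'", ext)
  allowed <- c("n_subjects", "seed", "height", "width", "window_side",
               "block_side", "outlier_k", "limit_green", "limit_blue",
               "clinical_threshold")
  bad <- setdiff(names(raw), allowed)
  if (length(bad))
    stopf("read_pipeline_config: unknown configuration key '%s'", bad[1])
  do.call(pipeline_config, raw)
}

# Canonical config hash for the provenance manifest: md5 of the canonical
# JSON serialisation (sorted keys, fixed precision).
config_hash <- function(config) {
  canon <- jsonlite::toJSON(
    list(n_subjects = config$n_subjects, seed = config$seed,
         height = config$height, width = config$width,
         window_side = config$window_side, block_side = config$block_side,
         outlier_k = config$outlier_k, limit_green = config$limit_green,
         limit_blue = config$limit_blue,
         clinical_threshold = config$clinical_threshold,
         tsb = config$tsb[c("meanlog", "sdlog", "lower", "upper")],
         effects = config$effects[c("alpha", "beta", "covariate_slopes",
                                    "sigma_subj", "sigma_pix")]),
    auto_unbox = TRUE, digits = 12)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(canon), tf)
  unname(tools::md5sum(tf))
}

write_manifest <- function(config, out_dir, extra = list()) {
  manifest <- c(list(package = "biliscreen",
                     version = as.character(utils::packageVersion("biliscreen")),
                     seed = config$seed, n_subjects = config$n_subjects,
                     config_hash = config_hash(config)), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Simulate a cohort and its image directory
#'
#' Samples a cohort, renders one glabella patch per subject (per-subject seeds
#' derived by counter from the root seed), and writes `cohort.csv`, one PNG
#' per subject under `images/`, and a provenance `manifest.json` recording the
#' seed and a hash of the full generation profile.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, a list with `subjects`, `image_paths`, `manifest`.
#' @export
simulate_study <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("simulate_study: cannot create '%s'", out_dir)
  subjects <- sample_cohort(cohort_config(
    n_subjects = config$n_subjects, tsb = config$tsb, seed = config$seed))
  paths <- character(config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    img <- render_image(subjects[i, ], config$effects,
                        height = config$height, width = config$width,
                        seed = derive_seed(config$seed, i))
    paths[i] <- file.path(out_dir, "images",
                          paste0(subjects$subject_id[i], ".png"))
    write_skin_image(img, paths[i])
  }
  utils::write.csv(subjects, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  manifest <- write_manifest(config, out_dir, list(stage = "simulate"))
  invisible(list(subjects = subjects, image_paths = paths, manifest = manifest))
}

#' Screen a simulated or real study directory
#'
#' Runs the full analysis over a directory produced by [simulate_study()] (or
#' laid out the same way: `cohort.csv` plus `images/<subject_id>.png`):
#' uniform-region selection, QC, intensity extraction, per-channel Pearson
#' correlation, discrimination-limit classification at the configured green
#' and blue limits, a full threshold scan per channel, and stepwise forward
#' regression of TsB on channel means and clinical covariates. QC-failed
#' images and subjects without TsB are excluded and logged to
#' `exclusions.csv`; the run aborts if more than half the images fail QC.
#'
#' Outputs under `out_dir`: `summaries.csv`, `correlations.csv`,
#' `screening.json`, `scan_green.csv`, `scan_blue.csv`, `regression.json`,
#' `exclusions.csv`, `manifest.json`. All outputs are deterministic functions
#' of the inputs and configuration.
#'
#' @param config a [pipeline_config()].
#' @param data_dir directory holding `cohort.csv` and `images/`.
#' @param out_dir report directory (created if missing).
#' @param verbose print exclusion log messages (default TRUE).
#' @return invisibly, a list with `summaries`, `correlations`, `screening`,
#'   `regression`, `exclusions`.
#' @export
screen_study <- function(config, data_dir, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort_path <- file.path(data_dir, "cohort.csv")
  if (!file.exists(cohort_path))
    stopf("screen_study: no cohort table at '%s'", cohort_path)
  subjects <- utils::read.csv(cohort_path, stringsAsFactors = FALSE)
  exclusions <- data.frame(subject_id = character(0), reason = character(0),
                           stringsAsFactors = FALSE)
  summaries <- list()
  n_qc_fail <- 0
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    path <- file.path(data_dir, "images", paste0(sid, ".png"))
    if (!file.exists(path)) {
      exclusions <- rbind(exclusions, data.frame(subject_id = sid,
                                                 reason = "image_missing"))
      next
    }
    img <- read_skin_image(path, subject_id = sid)
    mask <- select_uniform_region(img, config$window_side)
    qc <- qc_image(img, mask, config$qc)
    if (!qc$passed) {
      n_qc_fail <- n_qc_fail + 1
      exclusions <- rbind(exclusions, data.frame(
        subject_id = sid, reason = paste(qc$reasons, collapse = ";")))
      if (verbose)
        message(sprintf("excluded %s: %s", sid, paste(qc$reasons, collapse = ", ")))
      next
    }
    summaries[[sid]] <- extract_intensity(img, mask)
  }
  n_images <- sum(file.exists(file.path(data_dir, "images",
                                        paste0(subjects$subject_id, ".png"))))
  if (n_images > 0 && n_qc_fail > n_images / 2)
    stopf("screen_study: %d of %d images failed quality control", n_qc_fail, n_images)
  summaries <- do.call(rbind, summaries)
  rownames(summaries) <- NULL
  # drop subjects without a TsB value, mirroring missing reference data
  no_tsb <- subjects$subject_id[is.na(subjects$tsb_umol_l)]
  if (length(no_tsb)) {
    exclusions <- rbind(exclusions, data.frame(subject_id = no_tsb,
                                               reason = "tsb_missing"))
    if (verbose)
      message(sprintf("excluded %s: no TsB value", paste(no_tsb, collapse = ", ")))
  }
  analysed <- merge(
    stats::reshape(summaries[, c("subject_id", "channel", "mean")],
                   idvar = "subject_id", timevar = "channel",
                   direction = "wide"),
    subjects, by = "subject_id")
  names(analysed) <- sub("^mean\\.", "mean_", names(analysed))
  analysed <- analysed[!is.na(analysed$tsb_umol_l), ]
  analysed <- analysed[order(analysed$subject_id), ]
  correlations <- correlate_channels(summaries, subjects)
  screening <- list(
    green = classify_and_score(analysed$mean_green, analysed$tsb_umol_l,
                               config$limit_green, config$clinical_threshold),
    blue = classify_and_score(analysed$mean_blue, analysed$tsb_umol_l,
                              config$limit_blue, config$clinical_threshold))
  scans <- list(
    green = threshold_scan(analysed$mean_green, analysed$tsb_umol_l,
                           config$clinical_threshold),
    blue = threshold_scan(analysed$mean_blue, analysed$tsb_umol_l,
                          config$clinical_threshold))
  cand <- data.frame(mean_red = analysed$mean_red,
                     mean_green = analysed$mean_green,
                     mean_blue = analysed$mean_blue,
                     ga_weeks = analysed$ga_weeks,
                     age_days = analysed$age_days,
                     weight_g = analysed$weight_g,
                     hb_mmol_l = analysed$hb_mmol_l,
                     sex_male = as.numeric(analysed$sex == "male"))
  # constant candidates (e.g. a single-sex subset) carry no information
  cand <- cand[, vapply(cand, stats::sd, numeric(1)) > 0, drop = FALSE]
  regression <- if (nrow(analysed) > ncol(cand) + 2)
    stepwise_forward(analysed$tsb_umol_l, cand) else NULL
  # reports
  write_channel_summaries(summaries, file.path(out_dir, "summaries.csv"))
  utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                   row.names = FALSE)
  utils::write.csv(exclusions, file.path(out_dir, "exclusions.csv"),
                   row.names = FALSE)
  utils::write.csv(scans$green$scan, file.path(out_dir, "scan_green.csv"),
                   row.names = FALSE)
  utils::write.csv(scans$blue$scan, file.path(out_dir, "scan_blue.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(green = unclass(screening$green), blue = unclass(screening$blue),
         chosen_limit_green = scans$green$chosen_limit,
         chosen_limit_blue = scans$blue$chosen_limit),
    file.path(out_dir, "screening.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  regression_report <- if (is.null(regression)) {
    list(note = "too few analysed subjects for stepwise regression")
  } else {
    list(selected_terms = regression$selected_terms,
         coefficients = as.list(regression$coefficients),
         entry_p_values = regression$entry_p_values,
         n = regression$n, entry_alpha = regression$entry_alpha)
  }
  jsonlite::write_json(regression_report, file.path(out_dir, "regression.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_manifest(config, out_dir,
                 list(stage = "screen", n_analysed = nrow(analysed),
                      n_excluded = nrow(exclusions)))
  invisible(list(summaries = summaries, correlations = correlations,
                 screening = screening, scans = scans,
                 regression = regression, exclusions = exclusions,
                 analysed = analysed))
}

#' Run one simulated cohort through extraction and correlation
#'
#' Convenience in-memory pipeline used for calibration studies: samples a
#' cohort, renders every patch, selects the uniform region, extracts channel
#' means, and returns the per-channel intensity/TsB correlations without
#' touching disk.
#'
#' @param config a [pipeline_config()].
#' @return list with `subjects`, `means` (per-subject channel means), and
#'   `correlations` (as [correlate_channels()]).
#' @export
run_cohort_correlation <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  subjects <- sample_cohort(cohort_config(
    n_subjects = config$n_subjects, tsb = config$tsb, seed = config$seed))
  rows <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    img <- render_image(subjects[i, ], config$effects,
                        height = config$height, width = config$width,
                        seed = derive_seed(config$seed, i))
    mask <- select_uniform_region(img, config$window_side)
    rows[[i]] <- extract_intensity(img, mask)
  }
  summaries <- do.call(rbind, rows)
  means <- stats::reshape(summaries[, c("subject_id", "channel", "mean")],
                          idvar = "subject_id", timevar = "channel",
                          direction = "wide")
  names(means) <- sub("^mean\\.", "mean_", names(means))
  list(subjects = subjects, means = means,
       correlations = correlate_channels(summaries, subjects))
}
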