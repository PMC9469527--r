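# --- configuration ----------------------------------------------------------

#' Full pipeline configuration
#'
#' One document with a section per stage. Unknown keys in any section are
#' rejected so that every deviation from the defaults is visible.
#'
#' @param generator A [generator_config()] or a list of its fields.
#' @param preprocessing List: `sensor_area_cm2`, `k_trim`,
#'   `standing_window_s`, `min_steps` and a `threshold` sub-list
#'   ([threshold_params()] fields).
#' @param extraction List of [feature_control()] fields.
#' @param classification List: `targets`, `n_folds`, `n_repeats`,
#'   `n_trees`, `subgroups` (logical: fit the subgroup models too).
#' @param seed Optional master seed overriding `generator$seed`.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = list(), preprocessing = list(),
                            extraction = list(), classification = list(),
                            seed = NULL) {
  merge_section <- function(defaults, given, section) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown) > 0) {
      abort_config(section, paste0("unknown key(s): ",
                                   paste(unknown, collapse = ", ")))
    }
    utils::modifyList(defaults, given)
  }
  if (inherits(generator, "generator_config")) generator <- unclass(generator)
  gen <- merge_section(unclass(generator_config()), generator, "generator")
  if (!is.null(seed)) gen$seed <- seed
  pre_defaults <- list(sensor_area_cm2 = 1.0, k_trim = 2,
                       standing_window_s = 45, min_steps = 3,
                       threshold = threshold_params())
  pre <- merge_section(pre_defaults, preprocessing, "preprocessing")
  pre$threshold <- do.call(threshold_params,
                           merge_section(threshold_params(),
                                         pre$threshold, "threshold"))
  ext <- merge_section(feature_control(), extraction, "extraction")
  cls_defaults <- list(targets = c("frail", "faller"), n_folds = 5,
                       n_repeats = 100, n_trees = 200, subgroups = FALSE)
  cls <- merge_section(cls_defaults, classification, "classification")
  structure(list(
    generator = validate_generator_config(gen),
    preprocessing = pre, extraction = do.call(feature_control, ext),
    classification = cls), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path File path; dispatch on extension (`.yml`/`.yaml`/`.json`).
#' @return A validated [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort_data(sprintf("configuration file not found: %s", path))
  }
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("generator", "preprocessing", "extraction", "classification",
             "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort_config("config", paste0("unknown section(s): ",
                                  paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$generator$effect_size_multipliers)) {
    raw$generator$effect_size_multipliers <-
      purrr::map(raw$generator$effect_size_multipliers, unlist)
  }
  do.call(pipeline_config, raw)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(yaml::as.yaml(unclass_deep(x)))
  invisible(x)
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    x[] <- purrr::map(x, unclass_deep)
  }
  x
}

# --- artifact IO -------------------------------------------------------------

#' Write a cohort to disk
#'
#' One CSV per trial per subject (`<subject>_standing.csv` /
#' `<subject>_walking.csv` with columns `time_s`, `L1..L7`, `R1..R7` in
#' kPa), a `subjects.csv` metadata table and a `ground_truth.json` with
#' the true stance events.
#'
#' @param cohort An `insole_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- cohort$subjects
  readr::write_csv(s[, c("subject_id", "age", "sex", "frail", "faller")],
                   file.path(dir, "subjects.csv"))
  for (i in seq_len(nrow(s))) {
    readr::write_csv(as_tibble(s$standing[[i]]),
                     file.path(dir, paste0(s$subject_id[i], "_standing.csv")))
    readr::write_csv(as_tibble(s$walking[[i]]),
                     file.path(dir, paste0(s$subject_id[i], "_walking.csv")))
  }
  jsonlite::write_json(
    list(config = unclass_deep(cohort$config), truth = cohort$truth),
    file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = 15, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' Accepts any directory with the same layout: a `subjects.csv` and per
#' subject `<id>_standing.csv` / `<id>_walking.csv` pressure tables.
#'
#' @param dir Cohort directory.
#' @param sampling_rate Sampling rate of the recordings, Hz.
#' @return An `insole_cohort` (ground truth restored when present).
#' @export
read_cohort <- function(dir, sampling_rate = 100) {
  meta_path <- file.path(dir, "subjects.csv")
  if (!file.exists(meta_path)) {
    abort_data(sprintf("missing required file: %s", meta_path))
  }
  subjects <- readr::read_csv(meta_path, show_col_types = FALSE)
  read_rec <- function(id, trial) {
    p <- file.path(dir, paste0(id, "_", trial, ".csv"))
    if (!file.exists(p)) abort_data(sprintf("missing required file: %s", p))
    insole_recording(readr::read_csv(p, show_col_types = FALSE),
                     sampling_rate, "kPa", trial)
  }
  subjects$standing <- purrr::map(subjects$subject_id, read_rec, "standing")
  subjects$walking <- purrr::map(subjects$subject_id, read_rec, "walking")
  gt_path <- file.path(dir, "ground_truth.json")
  truth <- NULL
  config <- NULL
  if (file.exists(gt_path)) {
    gt <- jsonlite::fromJSON(gt_path)
    truth <- as_tibble(gt$truth)
    config <- gt$config
  }
  structure(list(subjects = subjects, truth = truth, config = config,
                 layout = sensor_layout()), class = "insole_cohort")
}

# --- pipeline stages ---------------------------------------------------------

#' Run the full analysis pipeline
#'
#' Generate (or load) a cohort, preprocess it, extract the feature table
#' and fit the classification models, writing a deterministic artifact
#' tree under `outdir`:
#' `cohort/` (per-trial CSVs, metadata, ground truth), `stances.csv`,
#' `features.csv` + `feature_dictionary.json`, `model_reports.json`,
#' `feature_ranks.csv` and `qc.json` (exclusions, unimodal-envelope
#' counts, imputations). The classification stage is skipped with a
#' logged reason when the cohort is too small for stratified folds.
#'
#' @param config A [pipeline_config()], or a path to a YAML/JSON config.
#' @param outdir Output directory.
#' @param seed Optional master seed override.
#' @return Invisibly, a list with the in-memory stage results
#'   (`cohort`, `preprocessed`, `features`, `models`, `importance`, `qc`).
#' @export
run_pipeline <- function(config = pipeline_config(), outdir, seed = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "pipeline_config")) {
    abort_config("config", "must be a pipeline_config or a file path")
  }
  if (!is.null(seed)) {
    gen <- unclass(config$generator)
    gen$seed <- seed
    config$generator <- validate_generator_config(gen)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  cohort <- generate_cohort(config$generator)
  write_cohort(cohort, file.path(outdir, "cohort"))

  pre <- config$preprocessing
  prep <- preprocess_cohort(cohort, pre$sensor_area_cm2, pre$threshold,
                            pre$k_trim, pre$standing_window_s,
                            pre$min_steps)
  readr::write_csv(
    dplyr::transmute(prep$stances, .data$subject_id, .data$foot,
                     .data$segment, .data$strike_s, .data$lift_s,
                     .data$duration_s),
    file.path(outdir, "stances.csv"))

  features <- extract_features(prep, config$extraction)
  features_imp <- impute_features(features)
  readr::write_csv(features_imp, file.path(outdir, "features.csv"))
  jsonlite::write_json(feature_dictionary(),
                       file.path(outdir, "feature_dictionary.json"),
                       auto_unbox = TRUE, digits = 15, pretty = TRUE)

  cls <- config$classification
  models <- NULL
  importance <- NULL
  skip_reason <- NULL
  min_class <- suppressWarnings(min(purrr::map_int(cls$targets, function(tg) {
    min(table(factor(features_imp[[tg]], levels = c("0", "1"))))
  })))
  if (nrow(features_imp) < 2 * cls$n_folds || min_class < cls$n_folds) {
    skip_reason <- sprintf(
      "classification skipped: smallest class has %d subjects, below the %d needed for stratified %d-fold CV",
      min_class, cls$n_folds, cls$n_folds)
    warn(skip_reason)
  } else {
    if (isTRUE(cls$subgroups)) {
      models <- subgroup_models(features_imp, cls$targets,
                                n_folds = cls$n_folds,
                                n_repeats = cls$n_repeats,
                                n_trees = cls$n_trees,
                                seed = config$generator$seed)
    } else {
      models <- purrr::imap(cls$targets, function(tg, i) {
        rep <- cross_validate(features_imp, tg, n_folds = cls$n_folds,
                              n_repeats = cls$n_repeats,
                              n_trees = cls$n_trees,
                              seed = config$generator$seed + i)
        dplyr::mutate(rep$summary, target = tg, subgroup = "whole_population",
                      skipped = FALSE, reason = NA_character_,
                      report = list(rep), .before = 1)
      }) |> list_rbind()
    }
    importance <- importance_ranking(features_imp, cls$targets[1],
                                     n_repeats = cls$n_repeats,
                                     n_trees = cls$n_trees,
                                     seed = config$generator$seed)
    readr::write_csv(importance$ranking,
                     file.path(outdir, "feature_ranks.csv"))
  }
  jsonlite::write_json(
    model_reports_json(models, skip_reason, config),
    file.path(outdir, "model_reports.json"),
    auto_unbox = TRUE, digits = 15, pretty = TRUE, na = "null")

  qc <- list(
    n_subjects = nrow(cohort$subjects),
    n_included = nrow(prep$subjects),
    exclusions = prep$exclusions,
    envelope_qc = attr(features, "qc"),
    imputations = attr(features_imp, "imputation_log")
  )
  jsonlite::write_json(qc, file.path(outdir, "qc.json"),
                       auto_unbox = TRUE, digits = 15, pretty = TRUE)

  invisible(list(cohort = cohort, preprocessed = prep,
                 features = features_imp, models = models,
                 importance = importance, qc = qc, outdir = outdir))
}

model_reports_json <- function(models, skip_reason, config) {
  if (is.null(models)) {
    return(list(skipped = TRUE, reason = skip_reason,
                config = unclass_deep(config)))
  }
  rows <- purrr::map(seq_len(nrow(models)), function(i) {
    row <- models[i, ]
    out <- list(target = row$target, subgroup = row$subgroup,
                n = row$n, skipped = row$skipped)
    if (!is.na(row$reason)) out$reason <- row$reason
    if (!row$skipped) {
      rep <- row$report[[1]]
      out$n_positive <- row$n_positive
      out$balanced_accuracy_mean <- row$balanced_accuracy_mean
      out$balanced_accuracy_sd <- row$balanced_accuracy_sd
      out$weighted_f1_mean <- row$weighted_f1_mean
      out$weighted_f1_sd <- row$weighted_f1_sd
      out$confusion <- unname(purrr::array_branch(rep$confusion, 1))
      out$confusion_row_normalized <-
        unname(purrr::array_branch(rep$confusion_norm, 1))
      out$repeat_seeds <- rep$repeat_seeds
    }
    out
  })
  list(skipped = FALSE, models = rows, config = unclass_deep(config))
}

#' Human-readable model summary table
#'
#' Renders the `model_reports.json` written by [run_pipeline()] as a
#' summary tibble, one row per attempted model.
#'
#' @param path Path to a `model_reports.json`.
#' @return Tibble with target, subgroup, n and metric columns.
#' @export
pipeline_report <- function(path) {
  if (!file.exists(path)) {
    abort_data(sprintf("missing required file: %s", path))
  }
  rep <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (isTRUE(rep$skipped)) {
    message(rep$reason)
    return(tibble(target = character(), subgroup = character()))
  }
  purrr::map(rep$models, function(m) {
    tibble(
      target = m$target, subgroup = m$subgroup, n = m$n,
      skipped = m$skipped,
      balanced_accuracy = if (m$skipped) NA_real_ else
        m$balanced_accuracy_mean,
      balanced_accuracy_sd = if (m$skipped) NA_real_ else
        m$balanced_accuracy_sd,
      weighted_f1 = if (m$skipped) NA_real_ else m$weighted_f1_mean,
      weighted_f1_sd = if (m$skipped) NA_real_ else m$weighted_f1_sd)
  }) |> list_rbind()
}
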