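#' Dictionary of the 182 extracted features
#'
#' One row per feature, in the fixed assembly order of
#' [extract_feature_vector()]: standing COP sway (4), frequency domain
#' (4), peak / AUC (84), single-foot COP trajectory (52), gait phase (8)
#' and envelope ("wavelet") analysis (30). `dimension` records how the
#' feature scales with a common force factor `c`: `force` and
#' `force_rate` scale by `c`, `power` by `c^2`, all others (`time`,
#' `length`, `area`, `ratio`, `percent`, `frequency`) are invariant.
#'
#' @return Tibble with `name`, `category`, `parameter`, `aggregation`,
#'   `sensor` (NA where not sensor-specific) and `dimension`.
#' @export
feature_dictionary <- function() {
  if (!is.null(.dict_cache$dict)) return(.dict_cache$dict)
  rows <- list()
  add <- function(name, category, parameter, aggregation, sensor, dim) {
    rows[[length(rows) + 1]] <<- tibble(
      name = name, category = category, parameter = parameter,
      aggregation = aggregation, sensor = sensor, dimension = dim)
  }
  for (p in c("range_x", "range_y", "path_length", "surface")) {
    add(paste0("standing_cop.", p), "standing_cop", p, "whole_trial",
        NA_integer_, if (p == "surface") "area" else "length")
  }
  fdim <- c(power_mean = "power", power_sd = "power",
            power_density = "power", mean_freq = "frequency")
  for (p in names(fdim)) {
    add(paste0("frequency.", p), "frequency", p, "whole_trial",
        NA_integer_, unname(fdim[p]))
  }
  aggs <- c("mean_left", "sd_left", "sd_both", "diff_lr")
  pdim <- c(max_pressure = "force", t_max_rel = "ratio", auc = "force")
  for (p in names(pdim)) {
    for (k in 1:7) {
      for (a in aggs) {
        add(sprintf("peak_auc.%s.%s.s%d", p, a, k), "peak_auc", p, a, k,
            unname(pdim[p]))
      }
    }
  }
  for (p in cop_1foot_parameter_names()) {
    for (a in aggs) {
      add(sprintf("cop_1foot.%s.%s", p, a), "cop_1foot", p, a, NA_integer_,
          if (p == "cpei") "ratio" else "length")
    }
  }
  gdim <- c(duration_s = "time", double_support_pct = "percent")
  for (p in names(gdim)) {
    for (a in aggs) {
      add(sprintf("gait_phase.%s.%s", p, a), "gait_phase", p, a,
          NA_integer_, unname(gdim[p]))
    }
  }
  wdim <- c(peak_distance = "time", h_peak1 = "force", h_peak2 = "force",
            h_valley = "force", h_peak_diff = "force",
            ratio_p1_valley = "ratio", ratio_p2_valley = "ratio",
            ratio_diff = "ratio", width_peak1 = "time",
            width_peak2 = "time", width_diff = "time",
            slope_start_p1 = "force_rate", slope_p1_valley = "force_rate",
            slope_valley_p2 = "force_rate", slope_p2_end = "force_rate")
  for (p in names(wdim)) {
    for (a in c("mean_left", "sd_left")) {
      add(sprintf("wavelet.%s.%s", p, a), "wavelet", p, a, NA_integer_,
          unname(wdim[p]))
    }
  }
  .dict_cache$dict <- list_rbind(rows)
  .dict_cache$dict
}

# memo for the (constant) dictionary; building it row-wise is not free
.dict_cache <- new.env(parent = emptyenv())

#' Names of the 182 features in assembly order
#' @return Character vector of length 182.
#' @export
feature_names <- function() feature_dictionary()$name

#' Extraction tuning parameters
#'
#' @param smooth_window Envelope smoothing window (samples) for landmark
#'   detection.
#' @param ratio_cap Cap on envelope peak/valley ratios.
#' @param band Frequency analysis band, Hz.
#' @param max_bin_hz Maximum spectral bin width, Hz.
#' @return Named list.
#' @export
feature_control <- function(smooth_window = 5, ratio_cap = 50,
                            band = c(2, 10), max_bin_hz = 0.5) {
  list(smooth_window = smooth_window, ratio_cap = ratio_cap,
       band = band, max_bin_hz = max_bin_hz)
}

#' Extract the 182-dimension feature vector of one subject
#'
#' Concatenates the six feature categories in fixed order: standing COP
#' sway (4), frequency domain (4), peak / AUC (84), single-foot COP
#' trajectory (52), gait phase (8) and envelope analysis (30). Per-stance
#' parameters that are undefined for a stance are excluded from their
#' aggregation; a feature with no valid stances at all is `NA` (imputed
#' downstream with the cohort or training-fold median).
#'
#' @param standing Windowed standing [insole_recording()] in N.
#' @param walking Walking [insole_recording()] in N.
#' @param stances The subject's trimmed stance tibble.
#' @param layout A [sensor_layout()].
#' @param control A [feature_control()] list.
#' @param context Untrimmed stance tibble used as contralateral context
#'   for support-transition parameters (defaults to `stances`).
#' @return Named numeric vector of length 182 with attribute `qc` (one-row
#'   tibble: unimodal envelope and capped-ratio counts).
#' @export
extract_feature_vector <- function(standing, walking, stances, layout,
                                   control = feature_control(),
                                   context = stances) {
  run <- function(category, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("feature extraction failed in category '%s': %s",
                    category, conditionMessage(e)),
            class = "insolegait_feature_error")
    })
  }
  v1 <- run("standing_cop", standing_cop_features(standing, layout))
  v2 <- run("frequency", frequency_features(
    walking_sum_series(walking, stances), recording_rate(walking),
    control$band, control$max_bin_hz))
  v3 <- run("peak_auc", peak_auc_features(walking, stances))
  v4 <- run("cop_1foot", cop_1foot_features(walking, stances, layout,
                                             context))
  v5 <- run("gait_phase", gait_phase_features(stances, context))
  v6 <- run("wavelet", wavelet_features(walking, stances,
                                        control$smooth_window,
                                        control$ratio_cap))
  qc <- attr(v6, "qc")
  out <- c(v1, v2, v3, v4, v5, v6)
  stopifnot(identical(names(out), feature_names()))
  attr(out, "qc") <- qc
  out
}

#' Extract the cohort feature table
#'
#' One row per included subject: `subject_id`, metadata columns and the
#' 182 feature columns (see [feature_dictionary()]).
#'
#' @param preprocessed An `insole_preprocessed` from [preprocess_cohort()].
#' @param control A [feature_control()] list.
#' @return Tibble of features with attribute `qc` (per-subject envelope QC
#'   counts).
#' @export
extract_features <- function(preprocessed, control = feature_control()) {
  subjects <- preprocessed$subjects
  layout <- preprocessed$layout
  rows <- purrr::map(seq_len(nrow(subjects)), function(i) {
    fv <- extract_feature_vector(
      subjects$standing[[i]], subjects$walking[[i]],
      subjects$stances[[i]], layout, control,
      context = subjects$stances_all[[i]] %||% subjects$stances[[i]])
    list(features = fv,
         qc = dplyr::mutate(attr(fv, "qc"),
                            subject_id = subjects$subject_id[i],
                            .before = 1))
  })
  meta_cols <- intersect(c("subject_id", "age", "sex", "frail", "faller"),
                         names(subjects))
  out <- dplyr::bind_cols(
    subjects[, meta_cols],
    as_tibble(do.call(rbind, purrr::map(rows, "features")))
  )
  attr(out, "qc") <- list_rbind(purrr::map(rows, "qc"))
  out
}

#' Impute missing feature values with column medians
#'
#' @param features Feature table from [extract_features()].
#' @param columns Columns to impute (defaults to the 182 feature columns).
#' @return The table with `NA`s replaced; attribute `imputation_log`
#'   records the affected columns and counts.
#' @export
impute_features <- function(features, columns = NULL) {
  if (is.null(columns)) columns <- intersect(feature_names(), names(features))
  log <- list()
  for (cl in columns) {
    miss <- !is.finite(features[[cl]])
    if (any(miss)) {
      med <- median(features[[cl]][!miss])
      features[[cl]][miss] <- med
      log[[length(log) + 1]] <- tibble(column = cl, n_imputed = sum(miss),
                                       value = med)
    }
  }
  attr(features, "imputation_log") <-
    if (length(log) > 0) list_rbind(log) else
      tibble(column = character(), n_imputed = integer(), value = numeric())
  features
}
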