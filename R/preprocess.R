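#' Convert raw pressures to per-sensor forces
#'
#' Converts every channel from kPa to Newtons assuming a constant
#' effective sensing area per sensor: `force_N = pressure_kPa * 1000 *
#' area_cm2 * 1e-4` (so 100 kPa on a 1 cm2 sensor = 10 N). The mapping is
#' linear and zero-preserving.
#'
#' @param recording An [insole_recording()] in kPa.
#' @param sensor_area_cm2 Effective sensing area per sensor in cm2.
#' @return The recording with all channels in N and units attribute `"N"`.
#' @export
convert_to_newtons <- function(recording, sensor_area_cm2 = 1.0) {
  if (recording_units(recording) != "kPa") {
    abort_data("recording is already in Newtons")
  }
  if (!is_pos(sensor_area_cm2)) {
    abort_config("sensor_area_cm2", "must be > 0")
  }
  ch <- channel_names()
  m <- as.matrix(recording[, ch])
  if (any(m < 0)) abort_data("negative pressures in recording")
  # kPa -> Pa (x1000), area cm2 -> m2 (x1e-4)
  recording[, ch] <- as_tibble(m * (sensor_area_cm2 * 0.1))
  attr(recording, "units") <- "N"
  recording
}

#' Stance detection threshold parameters
#'
#' The strike threshold defaults to 5% of the median peak stance force,
#' estimated in a first pass from regions exceeding 5% of the series
#' maximum. Hysteresis (lift threshold = `hysteresis` x strike threshold)
#' prevents chatter near the threshold; contacts shorter than
#' `min_contact_s` and swings shorter than `min_swing_s` are rejected.
#'
#' @param rel_threshold Strike threshold as fraction of median peak force.
#' @param hysteresis Lift threshold as a fraction of the strike threshold.
#' @param min_contact_s Minimum contact duration in s.
#' @param min_swing_s Minimum swing (off-ground) duration in s.
#' @return A named list.
#' @export
threshold_params <- function(rel_threshold = 0.05, hysteresis = 0.8,
                             min_contact_s = 0.1, min_swing_s = 0.1) {
  stopifnot(is_pos(rel_threshold), rel_threshold < 1,
            is_pos(hysteresis), hysteresis <= 1,
            is_pos(min_contact_s), is_pos(min_swing_s))
  list(rel_threshold = rel_threshold, hysteresis = hysteresis,
       min_contact_s = min_contact_s, min_swing_s = min_swing_s)
}

# runs of TRUE in a logical vector -> tibble(start, end) of 1-based
# inclusive indices
logical_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(start = starts[r$values], end = ends[r$values])
}

#' Detect stance phases from a single-foot total force series
#'
#' A stance starts at the first sample at or above the strike threshold
#' and ends at the first sample below the lift threshold, provided the
#' contact lasts at least `min_contact_s` and is separated from the next
#' contact by at least `min_swing_s` (shorter swings are bridged).
#' Intervals are half-open `[strike_idx, lift_idx)` in 1-based sample
#' indices; `strike_s = (strike_idx - 1) / rate`.
#'
#' @param force Numeric vector, one foot's total force (sum of 7 sensors).
#' @param sampling_rate Sampling rate in Hz.
#' @param params A [threshold_params()] list.
#' @return Tibble with `strike_idx`, `lift_idx`, `strike_s`, `lift_s`,
#'   `duration_s`, ordered and pairwise disjoint. Empty if no contact.
#' @export
detect_stances <- function(force, sampling_rate, params = threshold_params()) {
  if (length(force) < sampling_rate) {
    abort_data("force series must be at least 1 s long")
  }
  empty <- tibble(strike_idx = integer(), lift_idx = integer(),
                  strike_s = numeric(), lift_s = numeric(),
                  duration_s = numeric())
  if (max(force) <= 0) return(empty)

  # pass 1: provisional contacts above 5% of the series maximum give the
  # median peak stance force the final threshold is anchored to
  prov <- logical_runs(force >= 0.05 * max(force))
  if (nrow(prov) == 0) return(empty)
  peaks <- purrr::map_dbl(seq_len(nrow(prov)),
                          function(i) max(force[prov$start[i]:prov$end[i]]))
  thr <- params$rel_threshold * median(peaks)
  thr_lift <- params$hysteresis * thr

  # hysteresis state: 1 above strike threshold, 0 below lift threshold,
  # carry the previous state in between
  state <- rep(NA, length(force))
  state[force >= thr] <- 1
  state[force < thr_lift] <- 0
  if (is.na(state[1])) state[1] <- 0
  idx <- which(!is.na(state))
  state <- state[idx][cumsum(!is.na(state))][seq_along(state)]
  state <- as.logical(state)

  runs <- logical_runs(state)
  if (nrow(runs) == 0) return(empty)

  # bridge swings shorter than min_swing_s
  min_swing <- round(params$min_swing_s * sampling_rate)
  if (nrow(runs) > 1) {
    keep_sep <- (runs$start[-1] - runs$end[-nrow(runs)] - 1L) >= min_swing
    grp <- cumsum(c(TRUE, keep_sep))
    runs <- dplyr::summarise(dplyr::group_by(tibble(grp = grp, runs), grp),
                             start = min(.data$start), end = max(.data$end),
                             .groups = "drop")[, c("start", "end")]
  }
  # drop contacts shorter than min_contact_s
  min_contact <- round(params$min_contact_s * sampling_rate)
  runs <- dplyr::filter(runs, .data$end - .data$start + 1L >= min_contact)
  if (nrow(runs) == 0) return(empty)

  tibble(
    strike_idx = runs$start,
    lift_idx = runs$end + 1L,
    strike_s = (runs$start - 1) / sampling_rate,
    lift_s = runs$end / sampling_rate,
    duration_s = (runs$end + 1L - runs$start) / sampling_rate
  )
}

#' Detect stances on both feet of a walking recording
#'
#' Runs [detect_stances()] on each foot's summed force series and assigns
#' walking-segment membership: a new segment starts whenever a stance
#' begins more than `segment_gap_s` after every earlier lift (the
#' between-segment turnaround produces such a gap).
#'
#' @param recording A walking [insole_recording()] (kPa or N).
#' @param params A [threshold_params()] list.
#' @param segment_gap_s Minimum silent gap separating segments, s.
#' @return Tibble with `foot`, `segment`, `strike_idx`, `lift_idx`,
#'   `strike_s`, `lift_s`, `duration_s`, ordered by strike time.
#' @export
detect_walking_stances <- function(recording, params = threshold_params(),
                                   segment_gap_s = 1.0) {
  fs <- recording_rate(recording)
  st <- purrr::map(c("left", "right"), function(f) {
    dplyr::mutate(detect_stances(foot_total(recording, f), fs, params),
                  foot = f, .before = 1)
  }) |> list_rbind() |> dplyr::arrange(.data$strike_s)
  if (nrow(st) == 0) return(dplyr::mutate(st, segment = integer()))
  prev_max_lift <- cummax(dplyr::lag(st$lift_s, default = st$strike_s[1]))
  st$segment <- cumsum(c(TRUE, (st$strike_s - prev_max_lift)[-1] >
                           segment_gap_s))
  dplyr::select(st, "foot", "segment", dplyr::everything())
}

#' Remove acceleration and deceleration steps
#'
#' Walking segments begin and end at zero speed, so the first and last few
#' stances are not steady-state gait. Within each segment the first `k`
#' and last `k` stances (across both feet, in strike order) are dropped;
#' `k` defaults to 2 and may be set between 2 and 4, mirroring the usual
#' manual removal of two to four transient steps per 10 m segment.
#'
#' @param stances Stance tibble from [detect_walking_stances()] (must
#'   carry a `segment` column).
#' @param k Number of stances to trim from each end of each segment.
#' @return The trimmed stance tibble; a segment with fewer than `2k + 1`
#'   stances yields no stances and a warning.
#' @export
trim_transient_steps <- function(stances, k = 2) {
  if (!is_count(k) || k < 0) abort_config("k", "must be a non-negative count")
  if (!"segment" %in% names(stances)) {
    abort_data("stances must have a segment column")
  }
  out <- stances |>
    dplyr::group_by(.data$segment) |>
    dplyr::arrange(.data$strike_s, .by_group = TRUE) |>
    dplyr::mutate(.rank = dplyr::row_number(), .n = dplyr::n()) |>
    dplyr::ungroup()
  short <- unique(out$segment[out$.n <= 2 * k])
  if (length(short) > 0) {
    warn(sprintf("segment(s) %s have <= 2k stances; all stances removed",
                 paste(short, collapse = ", ")))
  }
  dplyr::filter(out, .data$.rank > k, .data$.rank <= .data$.n - k) |>
    dplyr::select(-".rank", -".n")
}

#' Apply the minimum-steps inclusion rule
#'
#' Subjects for whom fewer than `min_steps` stances were detected on
#' either foot (after transient-step trimming) are withdrawn from the
#' analysis.
#'
#' @param stances Stance tibble with `subject_id` and `foot` columns for
#'   the whole cohort.
#' @param subject_ids All subject ids that were processed (so subjects
#'   with zero detected stances are also logged).
#' @param min_steps Minimum stances required per foot.
#' @return List with `stances` (retained rows) and `exclusions`
#'   (tibble `subject_id`, `reason`).
#' @export
apply_inclusion_rule <- function(stances, subject_ids = NULL, min_steps = 3) {
  if (is.null(subject_ids)) subject_ids <- unique(stances$subject_id)
  counts <- stances |>
    dplyr::count(.data$subject_id, .data$foot) |>
    tidyr::pivot_wider(names_from = "foot", values_from = "n",
                       values_fill = 0L)
  for (f in c("left", "right")) if (!f %in% names(counts)) counts[[f]] <- 0L
  counts <- dplyr::full_join(tibble(subject_id = subject_ids), counts,
                             by = "subject_id") |>
    dplyr::mutate(dplyr::across(c("left", "right"), ~ tidyr::replace_na(., 0L)))
  excluded <- dplyr::filter(counts, .data$left < min_steps |
                              .data$right < min_steps)
  exclusions <- tibble(
    subject_id = excluded$subject_id,
    reason = sprintf("fewer than %d steps detected (left: %d, right: %d)",
                     min_steps, excluded$left, excluded$right)
  )
  list(
    stances = dplyr::filter(stances,
                            !.data$subject_id %in% excluded$subject_id),
    exclusions = exclusions
  )
}

#' Extract the standing analysis window
#'
#' Keeps exactly the last `window_s` seconds of a standing trial (the
#' start of the trial contains a settling transient).
#'
#' @param recording A standing [insole_recording()].
#' @param window_s Window length in s (default 45).
#' @return The windowed recording (`window_s * rate` samples, time
#'   rebased to 0).
#' @export
standing_window <- function(recording, window_s = 45) {
  fs <- recording_rate(recording)
  n_keep <- round(window_s * fs)
  if (nrow(recording) < n_keep) {
    abort_data(sprintf(
      "standing trial is %.2f s long; %.0f s are required",
      nrow(recording) / fs, window_s))
  }
  reslice_recording(recording, (nrow(recording) - n_keep + 1):nrow(recording))
}

#' Preprocess one subject's trials
#'
#' Full data-reduction chain for one subject: convert both trials to
#' Newtons, window the standing trial, detect and trim walking stances.
#'
#' @param standing,walking The subject's two [insole_recording()]s (kPa).
#' @param sensor_area_cm2 Per-sensor effective area for force conversion.
#' @param params [threshold_params()] for stance detection.
#' @param k_trim Transient stances trimmed per segment end.
#' @param standing_window_s Standing analysis window, s.
#' @return List with `standing` (windowed, N), `walking` (N), and
#'   `stances` (trimmed stance tibble).
#' @export
preprocess_subject <- function(standing, walking, sensor_area_cm2 = 1.0,
                               params = threshold_params(), k_trim = 2,
                               standing_window_s = 45) {
  standing_n <- convert_to_newtons(standing_window(standing,
                                                   standing_window_s),
                                   sensor_area_cm2)
  walking_n <- convert_to_newtons(walking, sensor_area_cm2)
  stances_all <- detect_walking_stances(walking_n, params)
  stances <- trim_transient_steps(stances_all, k = k_trim)
  # the full detected set stays available as contralateral context for
  # double-support computations on the retained stances
  list(standing = standing_n, walking = walking_n, stances = stances,
       stances_all = stances_all)
}

#' Preprocess a whole cohort
#'
#' Applies [preprocess_subject()] to every subject and the >= `min_steps`
#' per-foot inclusion rule to the cohort.
#'
#' @param cohort An `insole_cohort` (or a compatible list with a
#'   `subjects` tibble holding `standing` / `walking` list-columns).
#' @inheritParams preprocess_subject
#' @param min_steps Inclusion rule threshold.
#' @return List of class `insole_preprocessed`: `subjects` (retained
#'   subjects with list-columns `standing`, `walking` now in N and a
#'   `stances` list-column), `stances` (cohort-level stance tibble), and
#'   `exclusions`.
#' @export
preprocess_cohort <- function(cohort, sensor_area_cm2 = 1.0,
                              params = threshold_params(), k_trim = 2,
                              standing_window_s = 45, min_steps = 3) {
  subjects <- cohort$subjects
  pp <- purrr::map(seq_len(nrow(subjects)), function(i) {
    preprocess_subject(subjects$standing[[i]], subjects$walking[[i]],
                       sensor_area_cm2, params, k_trim, standing_window_s)
  })
  all_stances <- purrr::imap(pp, function(p, i) {
    dplyr::mutate(p$stances, subject_id = subjects$subject_id[i], .before = 1)
  }) |> list_rbind()

  incl <- apply_inclusion_rule(all_stances, subjects$subject_id, min_steps)
  keep <- !subjects$subject_id %in% incl$exclusions$subject_id

  subjects <- subjects[keep, ]
  subjects$standing <- purrr::map(pp[keep], "standing")
  subjects$walking <- purrr::map(pp[keep], "walking")
  subjects$stances <- purrr::map(pp[keep], "stances")
  subjects$stances_all <- purrr::map(pp[keep], "stances_all")

  structure(list(subjects = subjects, stances = incl$stances,
                 exclusions = incl$exclusions, layout = cohort$layout,
                 config = cohort$config),
            class = "insole_preprocessed")
}
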