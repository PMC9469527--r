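#' Configuration for the synthetic insole cohort generator
#'
#' Builds and validates the parameter set controlling [generate_cohort()].
#' The generator emulates the signal structure of a 7-sensor-per-foot
#' pressure insole sampled at 100 Hz: a standing balance trial with
#' low-frequency centre-of-pressure sway, and a walking trial of two
#' straight segments with alternating left/right stances whose per-sensor
#' pressure curves are heel-led, toe-terminated double-bump profiles.
#' Pressures are clipped to the sensor response ceiling of 550 kPa,
#' zeroed below the 25 kPa response floor, and quantised on a 10-bit
#' (1024-level) scale, matching the device's analog-to-digital converter.
#'
#' Group effects: `effect_size_multipliers` is a named list with optional
#' elements `frail` and `faller`, each a named numeric vector of
#' multipliers applied to a generative parameter for subjects carrying
#' that label (e.g. `list(frail = c(stance_duration_mean = 1.3))`).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param frail_fraction,faller_fraction Label prevalences in `[0,1]`.
#'   Defaults calibrated to a senior community cohort (roughly 29% frail,
#'   20% with a fall in the previous year).
#' @param sampling_rate Sampling rate in Hz.
#' @param standing_duration Standing trial length in s (the last 45 s are
#'   used downstream).
#' @param n_steps_per_segment Steps per foot per 10 m walking segment.
#' @param stance_duration_mean Mean stance-phase duration in s.
#' @param stance_duration_between_cv Between-subject coefficient of
#'   variation of stance duration.
#' @param stance_duration_cv Within-subject (stance-to-stance) CV.
#' @param peak_valley_ratio_mean Mean ratio of the stance force-envelope
#'   peak height to the mid-stance valley height (controls peak sharpness).
#' @param peak_valley_ratio_between_cv Between-subject CV of that ratio.
#' @param double_support_fraction Fraction of each stance spent in double
#'   support (split evenly between the leading and trailing episode).
#' @param sensor_noise_sd Gaussian sensor noise SD in kPa, applied to
#'   loaded samples (an unloaded sensor reads 0).
#' @param sway_x_mm,sway_y_mm Standing sway amplitude (SD of the COP
#'   excursion) on the medial-lateral and anterior-posterior axes, mm.
#' @param amplitude_between_cv Between-subject CV of overall pressure
#'   amplitude (body-mass / gait-vigour proxy).
#' @param insole_length_mm Insole length passed to [sensor_layout()].
#' @param effect_size_multipliers See Details.
#' @param seed Integer master seed; the cohort is a pure function of the
#'   configuration including the seed.
#'
#' @return A validated list of class `generator_config`.
#' @examples
#' cfg <- generator_config(n_subjects = 4, seed = 1)
#' @export
generator_config <- function(n_subjects = 100,
                             frail_fraction = 0.285,
                             faller_fraction = 0.2,
                             sampling_rate = 100,
                             standing_duration = 60,
                             n_steps_per_segment = 8,
                             stance_duration_mean = 0.70,
                             stance_duration_between_cv = 0.08,
                             stance_duration_cv = 0.05,
                             peak_valley_ratio_mean = 1.8,
                             peak_valley_ratio_between_cv = 0.10,
                             double_support_fraction = 0.20,
                             sensor_noise_sd = 4,
                             sway_x_mm = 5,
                             sway_y_mm = 8,
                             amplitude_between_cv = 0.08,
                             insole_length_mm = 250,
                             effect_size_multipliers = list(),
                             seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects, frail_fraction = frail_fraction,
    faller_fraction = faller_fraction, sampling_rate = sampling_rate,
    standing_duration = standing_duration,
    n_steps_per_segment = n_steps_per_segment,
    stance_duration_mean = stance_duration_mean,
    stance_duration_between_cv = stance_duration_between_cv,
    stance_duration_cv = stance_duration_cv,
    peak_valley_ratio_mean = peak_valley_ratio_mean,
    peak_valley_ratio_between_cv = peak_valley_ratio_between_cv,
    double_support_fraction = double_support_fraction,
    sensor_noise_sd = sensor_noise_sd,
    sway_x_mm = sway_x_mm, sway_y_mm = sway_y_mm,
    amplitude_between_cv = amplitude_between_cv,
    insole_length_mm = insole_length_mm,
    effect_size_multipliers = effect_size_multipliers,
    seed = seed
  )
  validate_generator_config(cfg)
}

validate_generator_config <- function(cfg) {
  if (!is_count(cfg$n_subjects) || cfg$n_subjects < 2) {
    abort_config("n_subjects", "must be an integer >= 2")
  }
  for (f in c("frail_fraction", "faller_fraction", "double_support_fraction")) {
    if (!is_prop(cfg[[f]])) abort_config(f, "must be a proportion in [0, 1]")
  }
  for (f in c("sampling_rate", "standing_duration", "stance_duration_mean",
              "peak_valley_ratio_mean", "sway_x_mm", "sway_y_mm",
              "insole_length_mm")) {
    if (!is_pos(cfg[[f]])) abort_config(f, "must be strictly positive")
  }
  for (f in c("stance_duration_cv", "stance_duration_between_cv",
              "peak_valley_ratio_between_cv", "sensor_noise_sd",
              "amplitude_between_cv")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 0) {
      abort_config(f, "must be a non-negative number")
    }
  }
  if (!is_count(cfg$n_steps_per_segment) || cfg$n_steps_per_segment < 1) {
    abort_config("n_steps_per_segment", "must be a positive integer")
  }
  if (!is_count(cfg$seed)) abort_config("seed", "must be an integer")
  if (!is.list(cfg$effect_size_multipliers)) {
    abort_config("effect_size_multipliers", "must be a named list")
  }
  bad <- setdiff(names(cfg$effect_size_multipliers), c("frail", "faller"))
  if (length(bad) > 0) {
    abort_config("effect_size_multipliers",
                 paste0("groups must be 'frail' or 'faller', not ",
                        paste(bad, collapse = ", ")))
  }
  for (grp in names(cfg$effect_size_multipliers)) {
    m <- cfg$effect_size_multipliers[[grp]]
    unknown <- setdiff(names(m), injectable_parameters())
    if (length(unknown) > 0) {
      abort_config("effect_size_multipliers",
                   paste0("unknown parameter(s) ",
                          paste(unknown, collapse = ", "),
                          "; valid names: ",
                          paste(injectable_parameters(), collapse = ", ")))
    }
    if (any(!is.finite(m)) || any(m <= 0)) {
      abort_config("effect_size_multipliers", "multipliers must be > 0")
    }
  }
  structure(cfg, class = "generator_config")
}

#' Generator parameters that accept group-effect multipliers
#' @return Character vector of parameter names.
#' @export
injectable_parameters <- function() {
  c("stance_duration_mean", "peak_valley_ratio_mean",
    "double_support_fraction", "sway_x_mm", "sway_y_mm",
    "amplitude_scale", "stance_duration_cv")
}

# pressure-curve shape constants per sensor (heel ... big toe):
# peak position on normalised stance time, log-normal width, amplitude (kPa)
# relative to the subject amplitude scale, and contact-floor load (kPa).
sensor_shape <- function(pv_ratio) {
  valley_amp <- 340 / pv_ratio
  list(
    m = c(0.20, 0.40, 0.50, 0.62, 0.72, 0.76, 0.83),
    s = c(0.30, 0.32, 0.32, 0.26, 0.24, 0.24, 0.20),
    amp = c(330, 0.85 * valley_amp, valley_amp, 250, 300, 270, 230),
    # heel carries a sharp landing load that decays over the stance;
    # the remaining floors only ride on top of the sensor bumps
    floor = c(80, 12, 12, 12, 12, 12, 10)
  )
}

lognorm_bump <- function(u, m, s) {
  out <- numeric(length(u))
  pos <- u > 0
  out[pos] <- exp(-(log(u[pos] / m))^2 / (2 * s^2))
  out
}

# multiplier for parameter `name` given a subject's labels
group_multiplier <- function(cfg, name, frail, faller) {
  mult <- 1
  esm <- cfg$effect_size_multipliers
  if (frail == 1 && !is.null(esm$frail) && name %in% names(esm$frail)) {
    mult <- mult * unname(esm$frail[[name]])
  }
  if (faller == 1 && !is.null(esm$faller) && name %in% names(esm$faller)) {
    mult <- mult * unname(esm$faller[[name]])
  }
  mult
}

# digitisation chain shared by both trials: loaded-sample noise, 25 kPa
# response deadband, 550 kPa ceiling, 10-bit quantisation
digitize_pressures <- function(p, noise_sd) {
  if (noise_sd > 0) {
    loaded <- p > 0
    p[loaded] <- p[loaded] + rnorm(sum(loaded), 0, noise_sd)
    p <- pmax(p, 0)
  }
  p[p < 25] <- 0
  p <- pmin(p, 550)
  round(p * (1023 / 550)) * (550 / 1023)
}

draw_subject_params <- function(cfg, frail, faller) {
  trunc_norm <- function(mean, cv, lo, hi) {
    min(max(mean * (1 + cv * rnorm(1)), lo), hi)
  }
  d_mean <- cfg$stance_duration_mean *
    group_multiplier(cfg, "stance_duration_mean", frail, faller)
  pv_mean <- cfg$peak_valley_ratio_mean *
    group_multiplier(cfg, "peak_valley_ratio_mean", frail, faller)
  list(
    stance_duration = trunc_norm(d_mean, cfg$stance_duration_between_cv,
                                 0.4 * d_mean, 2.5 * d_mean),
    stance_duration_cv = cfg$stance_duration_cv *
      group_multiplier(cfg, "stance_duration_cv", frail, faller),
    pv_ratio = trunc_norm(pv_mean, cfg$peak_valley_ratio_between_cv,
                          1.15, 4),
    double_support_fraction = min(cfg$double_support_fraction *
      group_multiplier(cfg, "double_support_fraction", frail, faller), 0.6),
    amplitude = trunc_norm(1, cfg$amplitude_between_cv, 0.6, 1.5) *
      group_multiplier(cfg, "amplitude_scale", frail, faller),
    sway_x = cfg$sway_x_mm *
      group_multiplier(cfg, "sway_x_mm", frail, faller) *
      trunc_norm(1, 0.15, 0.5, 1.6),
    sway_y = cfg$sway_y_mm *
      group_multiplier(cfg, "sway_y_mm", frail, faller) *
      trunc_norm(1, 0.15, 0.5, 1.6)
  )
}

# one subject's walking trial: two segments of alternating stances
synth_walking <- function(params, cfg) {
  fs <- cfg$sampling_rate
  ds <- params$double_support_fraction
  shp <- sensor_shape(params$pv_ratio)
  n_stances <- 2L * cfg$n_steps_per_segment

  events <- list()
  seg_start <- 1.0
  for (seg in 1:2) {
    t <- seg_start
    for (j in seq_len(n_stances)) {
      d <- params$stance_duration *
        max(1 + params$stance_duration_cv * rnorm(1), 0.4)
      strike_idx <- round(t * fs)
      dur_idx <- max(round(d * fs), 2L)
      events[[length(events) + 1]] <- tibble(
        segment = seg,
        foot = if (j %% 2 == 1) "left" else "right",
        strike_idx = strike_idx, lift_idx = strike_idx + dur_idx
      )
      t <- strike_idx / fs + (dur_idx / fs) * (1 - ds / 2)
    }
    last_lift <- events[[length(events)]]$lift_idx / fs
    seg_start <- last_lift + 2.5
  }
  events <- list_rbind(events)

  n_total <- max(events$lift_idx) + round(1.0 * fs)
  chans <- matrix(0, nrow = n_total, ncol = 14,
                  dimnames = list(NULL, channel_names()))
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    n <- e$lift_idx - e$strike_idx
    u <- (seq_len(n) - 0.5) / n
    t_in <- (seq_len(n) - 0.5) / fs
    t_rem <- n / fs - t_in
    w <- pmin(1, t_in / 0.005, t_rem / 0.020)
    rows <- (e$strike_idx + 1):e$lift_idx
    cols <- channel_names(e$foot)
    for (k in 1:7) {
      decay <- if (k == 1L) (1 - u) else 1
      curve <- params$amplitude *
        (shp$amp[k] * lognorm_bump(u, shp$m[k], shp$s[k]) +
           shp$floor[k] * w * decay)
      chans[rows, cols[k]] <- chans[rows, cols[k]] + curve
    }
  }
  chans[] <- digitize_pressures(as.numeric(chans), cfg$sensor_noise_sd)

  rec <- insole_recording(
    bind_cols(tibble(time_s = (seq_len(n_total) - 1) / fs),
              as_tibble(chans)),
    sampling_rate = fs, units = "kPa", trial = "walking"
  )
  truth <- dplyr::transmute(
    events, segment = .data$segment, foot = .data$foot,
    strike_s = .data$strike_idx / fs, lift_s = .data$lift_idx / fs
  )
  list(recording = rec, truth = truth)
}

# standing trial: band-limited (<= 1 Hz) CoP sway mapped back to sensor
# pressures through a spatial kernel around the sway point
synth_standing <- function(params, cfg, layout) {
  fs <- cfg$sampling_rate
  n <- round(cfg$standing_duration * fs)
  t <- (seq_len(n) - 1) / fs

  sway_component <- function(amp_mm) {
    f <- runif(4, 0.1, 1.0)
    a <- runif(4, 0.5, 1.0)
    ph <- runif(4, 0, 2 * pi)
    raw <- rowSums(vapply(1:4, function(k) a[k] * sin(2 * pi * f[k] * t + ph[k]),
                          numeric(n)))
    amp_mm * raw / max(sd(raw), 1e-9)
  }
  cx <- sway_component(params$sway_x)
  cy <- sway_component(params$sway_y)

  glob <- layout_global_standing(layout)
  base <- c(180, 60, 70, 120, 140, 130, 90) * params$amplitude
  chans <- matrix(0, nrow = n, ncol = 14,
                  dimnames = list(NULL, channel_names()))
  for (f in c("left", "right")) {
    pos <- dplyr::filter(glob, .data$foot == f) |> dplyr::arrange(.data$sensor)
    cols <- channel_names(f)
    for (k in 1:7) {
      kern <- exp(-((pos$x_mm[k] - cx)^2 / (2 * 70^2) +
                      (pos$y_mm[k] - cy)^2 / (2 * 90^2)))
      chans[, cols[k]] <- base[k] * kern
    }
  }
  chans[] <- digitize_pressures(as.numeric(chans), cfg$sensor_noise_sd)
  insole_recording(
    bind_cols(tibble(time_s = t), as_tibble(chans)),
    sampling_rate = fs, units = "kPa", trial = "standing"
  )
}

generate_subject <- function(subject_id, seed, frail, faller, cfg, layout) {
  withr::with_seed(seed, {
    params <- draw_subject_params(cfg, frail, faller)
    walking <- synth_walking(params, cfg)
    standing <- synth_standing(params, cfg, layout)
    list(params = params, standing = standing,
         walking = walking$recording,
         truth = dplyr::mutate(walking$truth, subject_id = subject_id,
                               .before = 1))
  })
}

#' Generate a synthetic labelled insole cohort
#'
#' Produces `n_subjects` subjects, each with one standing and one walking
#' trial (two 10 m segments), frailty / fall-history labels assigned as
#' deterministic counts (`round(fraction * n)`, shuffled by seed), and
#' ground-truth strike/lift times for every stance. The cohort is a pure
#' function of the configuration: identical configuration and seed
#' reproduce it bitwise.
#'
#' @param config A [generator_config()].
#' @return An object of class `insole_cohort`: a list with
#'   * `subjects`: tibble with `subject_id`, `age`, `sex`, `frail`,
#'     `faller`, `seed`, and list-columns `params`, `standing`, `walking`;
#'   * `truth`: tibble of ground-truth stance events
#'     (`subject_id`, `segment`, `foot`, `strike_s`, `lift_s`);
#'   * `config`: the generating configuration;
#'   * `layout`: the sensor layout used.
#' @examples
#' cohort <- generate_cohort(generator_config(n_subjects = 2, seed = 7))
#' cohort$subjects$frail
#' @export
generate_cohort <- function(config) {
  cfg <- validate_generator_config(config)
  layout <- sensor_layout(cfg$insole_length_mm)
  n <- cfg$n_subjects

  subjects <- withr::with_seed(cfg$seed, {
    n_frail <- round(cfg$frail_fraction * n)
    n_faller <- round(cfg$faller_fraction * n)
    tibble(
      subject_id = sprintf("S%04d", seq_len(n)),
      age = pmin(pmax(round(rnorm(n, 71.3, 8.2)), 60), 95),
      sex = ifelse(runif(n) < 505 / 712, "female", "male"),
      frail = sample(rep(c(1L, 0L), c(n_frail, n - n_frail))),
      faller = sample(rep(c(1L, 0L), c(n_faller, n - n_faller))),
      seed = sample.int(.Machine$integer.max - 1L, n)
    )
  })

  gen <- purrr::pmap(
    subjects[, c("subject_id", "seed", "frail", "faller")],
    function(subject_id, seed, frail, faller) {
      generate_subject(subject_id, seed, frail, faller, cfg, layout)
    }
  )
  subjects$params <- purrr::map(gen, "params")
  subjects$standing <- purrr::map(gen, "standing")
  subjects$walking <- purrr::map(gen, "walking")
  truth <- purrr::map(gen, "truth") |> list_rbind()

  structure(list(subjects = subjects, truth = truth,
                 config = cfg, layout = layout),
            class = "insole_cohort")
}

#' @export
print.insole_cohort <- function(x, ...) {
  cat(sprintf(
    "<insole cohort: %d subjects (%d frail, %d fallers), seed %d>\n",
    nrow(x$subjects), sum(x$subjects$frail), sum(x$subjects$faller),
    x$config$seed))
  invisible(x)
}

#' Inject a group difference into an existing cohort
#'
#' Scales one generative parameter for all subjects of a labelled group
#' (frail or faller) and deterministically re-synthesises their
#' recordings (per-subject seeds are retained, so only the injected
#' parameter changes). Enables parameter-recovery experiments: an effect
#' injected here should surface in the extracted features and in the
#' classifier's importance ranking.
#'
#' @param cohort An `insole_cohort` from [generate_cohort()].
#' @param parameter_name One of [injectable_parameters()].
#' @param multiplier Positive scalar applied to the group's parameter.
#' @param group `"frail"` or `"faller"`.
#' @return The modified cohort (ground truth updated).
#' @export
inject_group_effect <- function(cohort, parameter_name, multiplier,
                                group = c("frail", "faller")) {
  group <- match.arg(group)
  if (!parameter_name %in% injectable_parameters()) {
    abort_config("parameter_name",
                 paste0("unknown parameter '", parameter_name,
                        "'; valid names: ",
                        paste(injectable_parameters(), collapse = ", ")))
  }
  if (!is_pos(multiplier)) abort_config("multiplier", "must be > 0")

  cfg <- cohort$config
  esm <- cfg$effect_size_multipliers
  if (is.null(esm[[group]])) esm[[group]] <- numeric()
  esm[[group]][parameter_name] <- multiplier
  cfg$effect_size_multipliers <- esm
  cfg <- validate_generator_config(cfg)

  affected <- which(cohort$subjects[[group]] == 1L)
  for (i in affected) {
    s <- cohort$subjects[i, ]
    regen <- generate_subject(s$subject_id, s$seed, s$frail, s$faller,
                              cfg, cohort$layout)
    cohort$subjects$params[[i]] <- regen$params
    cohort$subjects$standing[[i]] <- regen$standing
    cohort$subjects$walking[[i]] <- regen$walking
    cohort$truth <- dplyr::bind_rows(
      dplyr::filter(cohort$truth, .data$subject_id != s$subject_id),
      regen$truth
    ) |> dplyr::arrange(.data$subject_id, .data$segment, .data$strike_s)
  }
  cohort$config <- cfg
  cohort
}
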