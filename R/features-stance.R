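# --- per-stance parameter tables and their 4-statistic aggregation -------

# sub-matrix (samples x 7 sensors) of one stance
stance_forces <- function(recording, strike_idx, lift_idx, foot) {
  foot_channels(recording, foot)[strike_idx:(lift_idx - 1L), , drop = FALSE]
}

# the four trial-level statistics applied to every per-stance parameter:
# mean over left stances, SD over left stances, SD over all stances of
# both feet, and the left-minus-right mean difference
aggregate_stats <- function(values, feet) {
  vl <- values[feet == "left"]
  vr <- values[feet == "right"]
  safe <- function(x) if (is.finite(x)) x else NA_real_
  c(mean_left = safe(mean(vl, na.rm = TRUE)),
    sd_left = safe(sd(vl[is.finite(vl)])),
    sd_both = safe(sd(values[is.finite(values)])),
    diff_lr = safe(mean(vl, na.rm = TRUE) - mean(vr, na.rm = TRUE)))
}

#' Per-stance peak and area-under-curve parameters
#'
#' For every stance and every sensor: the maximum force, the time of that
#' maximum relative to total stance time (first occurrence, in `[0, 1]`),
#' and the area under the force curve after resampling the stance onto a
#' 100-point band on normalised time `[0, 1]` (linear interpolation,
#' trapezoid rule on the normalised axis, so the AUC has force units).
#'
#' @param recording Walking [insole_recording()] in N.
#' @param stances Trimmed stance tibble for the subject.
#' @return Long tibble: `stance_id`, `foot`, `sensor`, `max_pressure`,
#'   `t_max_rel`, `auc`.
#' @export
peak_auc_stance_table <- function(recording, stances) {
  n_st <- nrow(stances)
  u100 <- seq(0, 1, length.out = 100)
  rows <- n_st * 7L
  stance_id <- rep(seq_len(n_st), each = 7L)
  foot <- rep(stances$foot, each = 7L)
  sensor <- rep.int(1:7, n_st)
  max_pressure <- t_max_rel <- auc <- numeric(rows)
  for (i in seq_len(n_st)) {
    m <- stance_forces(recording, stances$strike_idx[i],
                       stances$lift_idx[i], stances$foot[i])
    n <- nrow(m)
    u <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
    for (k in 1:7) {
      y <- m[, k]
      imax <- which.max(y)
      y100 <- if (n > 1) approx(u, y, xout = u100)$y else rep(y, 100)
      j <- (i - 1L) * 7L + k
      max_pressure[j] <- y[imax]
      t_max_rel[j] <- if (n > 1) (imax - 1) / (n - 1) else 0
      auc[j] <- trapz(u100, y100)
    }
  }
  tibble(stance_id = stance_id, foot = foot, sensor = sensor,
         max_pressure = max_pressure, t_max_rel = t_max_rel, auc = auc)
}

#' Peak / AUC feature block (84 features)
#'
#' Aggregates [peak_auc_stance_table()] with the four trial statistics
#' for each of the 3 parameters x 7 sensors.
#'
#' @inheritParams peak_auc_stance_table
#' @return Named numeric vector of 84 features
#'   `peak_auc.<parameter>.<aggregation>.s<sensor>`.
#' @export
peak_auc_features <- function(recording, stances) {
  tab <- peak_auc_stance_table(recording, stances)
  out <- numeric(0)
  for (param in c("max_pressure", "t_max_rel", "auc")) {
    for (k in 1:7) {
      sub <- dplyr::filter(tab, .data$sensor == k)
      v <- aggregate_stats(sub[[param]], sub$foot)
      names(v) <- sprintf("peak_auc.%s.%s.s%d", param, names(v), k)
      out <- c(out, v)
    }
  }
  out
}

#' Per-stance single-foot COP trajectory parameters
#'
#' For every stance the COP path of the loaded foot is computed and 13
#' parameters extracted: min/max on x and y; the (x, y) coordinates at the
#' double-to-single and single-to-double support transitions (the lift and
#' strike of the opposite foot within the stance); the x coordinate where
#' the path first crosses, moving anteriorly, the y level of the centre
#' midfoot and of the centre forefoot sensor; the range on x and y; and
#' the COP excursion index (CPEI), the maximum perpendicular deviation of
#' the path from its start-to-end chord divided by the lateral-medial
#' forefoot sensor distance. Parameters that are undefined for a stance
#' (e.g. a never-crossed reference level) are `NA` and excluded from
#' aggregation.
#'
#' @param recording Walking [insole_recording()] in N.
#' @param stances Trimmed stance tibble for the subject.
#' @param layout A [sensor_layout()].
#' @param context Stance tibble supplying the opposite foot's events for
#'   the support transitions; defaults to `stances`, but passing the
#'   untrimmed detected set keeps transitions of boundary stances intact.
#' @return Long tibble with `stance_id`, `foot` and the 13 parameters.
#' @export
cop_1foot_stance_table <- function(recording, stances, layout,
                                   context = stances) {
  fs <- recording_rate(recording)
  w_ff <- forefoot_sensor_distance(layout)
  pos_by_foot <- purrr::map(
    stats::setNames(nm = c("left", "right")),
    function(f) dplyr::arrange(dplyr::filter(layout, .data$foot == f),
                               .data$sensor))
  vals <- matrix(NA_real_, nrow(stances), 13,
                 dimnames = list(NULL, cop_1foot_parameter_names()))
  for (i in seq_len(nrow(stances))) {
    st <- stances[i, ]
    pos <- pos_by_foot[[st$foot]]
    m <- stance_forces(recording, st$strike_idx, st$lift_idx, st$foot)
    p <- compute_cop(m, pos)
    x <- p$x_mm
    y <- p$y_mm
    ok <- is.finite(x) & is.finite(y)

    opp <- context[context$foot != st$foot, ]
    cop_at <- function(t_s) {
      if (is.na(t_s)) return(c(NA_real_, NA_real_))
      j <- min(max(round((t_s - st$strike_s) * fs) + 1L, 1L), nrow(m))
      c(x[j], y[j])
    }
    t_d2s <- opp$lift_s[opp$lift_s > st$strike_s & opp$lift_s < st$lift_s]
    t_s2d <- opp$strike_s[opp$strike_s > st$strike_s &
                            opp$strike_s < st$lift_s]
    d2s <- cop_at(if (length(t_d2s) > 0) t_d2s[1] else NA)
    s2d <- cop_at(if (length(t_s2d) > 0) t_s2d[1] else NA)

    vals[i, ] <- c(
      if (any(ok)) min(x[ok]) else NA_real_,
      if (any(ok)) max(x[ok]) else NA_real_,
      if (any(ok)) min(y[ok]) else NA_real_,
      if (any(ok)) max(y[ok]) else NA_real_,
      d2s[1], d2s[2], s2d[1], s2d[2],
      x_at_y_crossing(x, y, pos$y_mm[pos$sensor == 3L]),
      x_at_y_crossing(x, y, pos$y_mm[pos$sensor == 5L]),
      if (any(ok)) diff(range(x[ok])) else NA_real_,
      if (any(ok)) diff(range(y[ok])) else NA_real_,
      cpei(x, y, w_ff)
    )
  }
  dplyr::bind_cols(tibble(stance_id = seq_len(nrow(stances)),
                          foot = stances$foot),
                   as_tibble(vals))
}

cop_1foot_parameter_names <- function() {
  c("min_x", "max_x", "min_y", "max_y", "x_d2s", "y_d2s", "x_s2d", "y_s2d",
    "x_at_midfoot_y", "x_at_forefoot_y", "range_x", "range_y", "cpei")
}

#' Single-foot COP feature block (52 features)
#'
#' @inheritParams cop_1foot_stance_table
#' @return Named numeric vector of 52 features
#'   `cop_1foot.<parameter>.<aggregation>`.
#' @export
cop_1foot_features <- function(recording, stances, layout,
                               context = stances) {
  tab <- cop_1foot_stance_table(recording, stances, layout, context)
  out <- numeric(0)
  for (param in cop_1foot_parameter_names()) {
    v <- aggregate_stats(tab[[param]], tab$foot)
    names(v) <- sprintf("cop_1foot.%s.%s", param, names(v))
    out <- c(out, v)
  }
  out
}

#' Per-stance gait-phase parameters
#'
#' Stance-phase duration and the percentage of the stance spent in double
#' support (total time during the stance in which the opposite foot is
#' also in contact).
#'
#' @param stances Trimmed stance tibble for the subject (both feet).
#' @param context Stance tibble supplying the opposite foot's contacts
#'   (defaults to `stances`; pass the untrimmed set so boundary stances
#'   keep both double-support episodes).
#' @return Tibble `stance_id`, `foot`, `duration_s`, `double_support_pct`.
#' @export
gait_phase_stance_table <- function(stances, context = stances) {
  if (length(unique(context$foot)) < 2) {
    abort_data("double-support computation needs stances from both feet")
  }
  overlap <- purrr::map_dbl(seq_len(nrow(stances)), function(i) {
    opp <- context[context$foot != stances$foot[i], ]
    sum(pmax(0, pmin(opp$lift_s, stances$lift_s[i]) -
               pmax(opp$strike_s, stances$strike_s[i])))
  })
  tibble(stance_id = seq_len(nrow(stances)), foot = stances$foot,
         duration_s = stances$duration_s,
         double_support_pct = 100 * overlap / stances$duration_s)
}

#' Gait-phase feature block (8 features)
#'
#' @inheritParams gait_phase_stance_table
#' @return Named numeric vector of 8 features
#'   `gait_phase.<parameter>.<aggregation>`.
#' @export
gait_phase_features <- function(stances, context = stances) {
  tab <- gait_phase_stance_table(stances, context)
  out <- numeric(0)
  for (param in c("duration_s", "double_support_pct")) {
    v <- aggregate_stats(tab[[param]], tab$foot)
    names(v) <- sprintf("gait_phase.%s.%s", param, names(v))
    out <- c(out, v)
  }
  out
}
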