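#' Centre of pressure of sensor force frames
#'
#' The COP is the force-weighted centroid of the sensor positions. Frames
#' with zero total force have no defined COP and yield `NA` coordinates
#' (callers skip and log them).
#'
#' @param forces Numeric matrix (frames x sensors) or a single frame
#'   vector; column k corresponds to row k of `positions`.
#' @param positions Data frame with `x_mm`, `y_mm`, one row per sensor in
#'   column order of `forces`.
#' @return Tibble with `x_mm`, `y_mm`, one row per frame.
#' @examples
#' lay <- dplyr::filter(sensor_layout(), foot == "left")
#' compute_cop(c(10, 0, 0, 0, 0, 0, 0), lay)  # heel only -> heel position
#' @export
compute_cop <- function(forces, positions) {
  if (is.null(dim(forces))) forces <- matrix(forces, nrow = 1)
  if (ncol(forces) != nrow(positions)) {
    abort_data("forces must have one column per sensor position")
  }
  total <- rowSums(forces)
  x <- as.numeric(forces %*% positions$x_mm) / total
  y <- as.numeric(forces %*% positions$y_mm) / total
  undef <- total <= 0
  x[undef] <- NA_real_
  y[undef] <- NA_real_
  tibble(x_mm = x, y_mm = y)
}

#' COP trajectory of a recording
#'
#' Two-foot (standing, 14 sensors in the global standing frame) or
#' one-foot trajectory over all samples of a recording.
#'
#' @param recording An [insole_recording()] (any units; COP is invariant
#'   to a common force scale).
#' @param layout A [sensor_layout()] covering the required feet.
#' @param foot `"both"` for the two-foot standing COP, else `"left"` or
#'   `"right"`.
#' @return Tibble `time_s`, `x_mm`, `y_mm`; undefined samples are `NA`.
#' @export
cop_path <- function(recording, layout, foot = "both") {
  if (foot == "both") {
    glob <- layout_global_standing(layout) |>
      dplyr::arrange(.data$foot, .data$sensor)
    # channel order must match position order (left then right, sensor 1-7)
    m <- as.matrix(recording[, c(channel_names("left"),
                                 channel_names("right"))])
    pos <- dplyr::bind_rows(dplyr::filter(glob, .data$foot == "left"),
                            dplyr::filter(glob, .data$foot == "right"))
  } else {
    m <- foot_channels(recording, foot)
    pos <- dplyr::filter(layout, .data$foot == !!foot) |>
      dplyr::arrange(.data$sensor)
  }
  dplyr::bind_cols(tibble(time_s = recording$time_s), compute_cop(m, pos))
}

# geometry of a finished COP path (NA samples dropped)
path_metrics <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) == 0) {
    return(list(range_x = NA_real_, range_y = NA_real_,
                path_length = NA_real_, surface = NA_real_, n = 0L))
  }
  list(
    range_x = diff(range(x)),
    range_y = diff(range(y)),
    path_length = sum(sqrt(diff(x)^2 + diff(y)^2)),
    surface = convex_hull_area(x, y),
    n = length(x)
  )
}

# maximum perpendicular deviation of a path from its start->end chord,
# divided by `norm` (the lateral-medial forefoot sensor distance)
cpei <- function(x, y, norm) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) return(NA_real_)
  dx <- x[length(x)] - x[1]
  dy <- y[length(y)] - y[1]
  chord <- sqrt(dx^2 + dy^2)
  if (chord <= .Machine$double.eps) return(NA_real_)
  dev <- abs(dx * (y - y[1]) - dy * (x - x[1])) / chord
  max(dev) / norm
}

# interpolated x where the path first crosses y = y_ref going anterior
# (y increasing); NA when no such crossing exists
x_at_y_crossing <- function(x, y, y_ref) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(y)
  if (n < 2) return(NA_real_)
  hit <- which(y[-n] <= y_ref & y[-1] >= y_ref & y[-1] > y[-n])
  if (length(hit) == 0) {
    exact <- which(y == y_ref)
    return(if (length(exact) > 0) x[exact[1]] else NA_real_)
  }
  i <- hit[1]
  f <- (y_ref - y[i]) / (y[i + 1] - y[i])
  x[i] + f * (x[i + 1] - x[i])
}
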