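#' Construct an insole recording
#'
#' An insole recording is a tibble with a `time_s` column and 14 pressure
#' channels `L1..L7`, `R1..R7` (sensor numbering of [sensor_layout()]),
#' carrying `sampling_rate`, `units` (`"kPa"` for raw pressure or `"N"` for
#' converted per-sensor force) and `trial` (`"standing"` or `"walking"`)
#' as attributes.
#'
#' @param data Data frame with columns `time_s`, `L1..L7`, `R1..R7`.
#' @param sampling_rate Sampling rate in Hz.
#' @param units `"kPa"` or `"N"`.
#' @param trial `"standing"` or `"walking"`.
#' @return A tibble of class `insole_recording`.
#' @export
insole_recording <- function(data, sampling_rate, units = c("kPa", "N"),
                             trial = c("walking", "standing")) {
  units <- match.arg(units)
  trial <- match.arg(trial)
  cols <- c("time_s", channel_names())
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort_data(paste0("recording is missing columns: ",
                      paste(missing, collapse = ", ")))
  }
  if (!is_pos(sampling_rate)) abort_config("sampling_rate", "must be > 0")
  dt <- diff(data$time_s)
  if (length(dt) > 0 && any(abs(dt - 1 / sampling_rate) > 1e-6)) {
    abort_data("recording timestamps are not uniform at the sampling rate")
  }
  out <- as_tibble(data[, cols])
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "units") <- units
  attr(out, "trial") <- trial
  class(out) <- c("insole_recording", class(out))
  out
}

channel_names <- function(foot = NULL) {
  if (is.null(foot)) return(c(paste0("L", 1:7), paste0("R", 1:7)))
  paste0(ifelse(foot == "left", "L", "R"), 1:7)
}

#' @export
print.insole_recording <- function(x, ...) {
  cat(sprintf("<insole recording: %s trial, %.1f s at %g Hz, units %s>\n",
              recording_trial(x), nrow(x) / recording_rate(x),
              recording_rate(x), recording_units(x)))
  NextMethod()
}

#' Recording attribute accessors
#'
#' @param recording An [insole_recording()].
#' @return Sampling rate in Hz, units string, or trial kind.
#' @export
recording_rate <- function(recording) {
  r <- attr(recording, "sampling_rate")
  if (is.null(r)) abort_data("recording has no sampling_rate attribute")
  r
}

#' @rdname recording_rate
#' @export
recording_units <- function(recording) attr(recording, "units") %||% "kPa"

#' @rdname recording_rate
#' @export
recording_trial <- function(recording) attr(recording, "trial") %||% "walking"

# 7-channel matrix for one foot
foot_channels <- function(recording, foot) {
  as.matrix(recording[, channel_names(foot)])
}

# per-foot total force/pressure series
foot_total <- function(recording, foot) {
  rowSums(foot_channels(recording, foot))
}

# keep recording attributes after a row subset
reslice_recording <- function(recording, rows) {
  out <- recording[rows, , drop = FALSE]
  out$time_s <- out$time_s - out$time_s[1]
  attr(out, "sampling_rate") <- attr(recording, "sampling_rate")
  attr(out, "units") <- attr(recording, "units")
  attr(out, "trial") <- attr(recording, "trial")
  class(out) <- class(recording)
  out
}
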