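#' Frequency-domain features of the summed walking force series
#'
#' The 14 sensor outputs are summed at each sampling time into a single
#' series; its magnitude-squared spectrum (fast Fourier transform of the
#' de-meaned series, rectangular window, one-sided, normalised by series
#' length) is summarised over the 2-10 Hz band:
#' mean power, standard deviation of power, power density (trapezoid
#' integral of power over the band, power x Hz) and the power-weighted
#' mean frequency. Zero-padding enforces a frequency resolution of at
#' most `max_bin_hz`.
#'
#' @param series Numeric vector, the summed 14-channel force series of the
#'   trimmed walking data (see [walking_sum_series()]).
#' @param sampling_rate Sampling rate, Hz.
#' @param band Analysis band in Hz.
#' @param max_bin_hz Maximum bin width; the series is zero-padded until
#'   the resolution is at least this fine.
#' @return Named numeric vector: `frequency.power_mean`,
#'   `frequency.power_sd`, `frequency.power_density`,
#'   `frequency.mean_freq`.
#' @export
frequency_features <- function(series, sampling_rate, band = c(2, 10),
                               max_bin_hz = 0.5) {
  if (length(series) < 2 * sampling_rate) {
    abort_data("summed force series must be at least 2 s long")
  }
  x <- series - mean(series)
  n <- length(x)
  n_pad <- max(n, ceiling(sampling_rate / max_bin_hz))
  x <- c(x, numeric(n_pad - n))
  spec <- Mod(fft(x))^2 / n
  freqs <- (seq_len(n_pad) - 1) * sampling_rate / n_pad
  half <- freqs <= sampling_rate / 2
  spec <- spec[half]
  freqs <- freqs[half]
  in_band <- freqs >= band[1] & freqs <= band[2]
  p <- spec[in_band]
  f <- freqs[in_band]
  total <- sum(p)
  c(frequency.power_mean = mean(p),
    frequency.power_sd = sd(p),
    frequency.power_density = trapz(f, p),
    frequency.mean_freq = if (total > 0) sum(f * p) / total else NA_real_)
}

#' Summed force series of the trimmed walking data
#'
#' Concatenates, per segment, the sum of the 14 channels from the first
#' retained strike to the last retained lift, excluding the trimmed
#' transient steps and the between-segment turnaround.
#'
#' @param recording Walking [insole_recording()] in N.
#' @param stances Trimmed stance tibble for this subject (needs `segment`,
#'   `strike_idx`, `lift_idx`).
#' @return Numeric vector.
#' @export
walking_sum_series <- function(recording, stances) {
  total <- foot_total(recording, "left") + foot_total(recording, "right")
  segs <- sort(unique(stances$segment))
  unlist(purrr::map(segs, function(s) {
    st <- dplyr::filter(stances, .data$segment == s)
    total[min(st$strike_idx):(max(st$lift_idx) - 1L)]
  }), use.names = FALSE)
}
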