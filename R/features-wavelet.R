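# --- stance force-envelope ("wavelet") analysis ---------------------------

#' Force envelope of a stance
#'
#' Per-sample maximum over the 7 channels of the loaded foot; during a
#' stance this traces the characteristic two-peak / one-valley ground
#' reaction pattern (heel loading and push-off).
#'
#' @param recording Walking [insole_recording()] in N.
#' @param strike_idx,lift_idx Half-open stance interval (1-based samples).
#' @param foot `"left"` or `"right"`.
#' @return Numeric vector of envelope forces (N).
#' @export
stance_envelope <- function(recording, strike_idx, lift_idx, foot = "left") {
  row_max(stance_forces(recording, strike_idx, lift_idx, foot))
}

# first-plateau-sample local maxima (ends eligible)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 2) return(integer())
  prev <- c(-Inf, x[-n])
  nxt <- c(x[-1], -Inf)
  which(x > prev & x >= nxt)
}

# refine a smoothed-envelope landmark on the raw envelope within the
# smoothing half-window
refine_index <- function(env, idx, half, what = c("max", "min")) {
  what <- match.arg(what)
  lo <- max(1L, idx - half)
  hi <- min(length(env), idx + half)
  win <- env[lo:hi]
  lo - 1L + if (what == "max") which.max(win) else which.min(win)
}

# horizontal extent of a peak at `frac` of its height (measured from
# zero), bounded by the adjacent valley / stance endpoints; linear
# interpolation of the crossing points; result in samples
peak_width_samples <- function(env, peak_idx, lo_bound, hi_bound,
                               frac = 0.3) {
  level <- frac * env[peak_idx]
  left <- lo_bound
  if (peak_idx > lo_bound) {
    for (j in (peak_idx - 1L):lo_bound) {
      if (env[j] < level) {
        left <- j + (level - env[j]) / (env[j + 1L] - env[j])
        break
      }
    }
  }
  right <- hi_bound
  if (peak_idx < hi_bound) {
    for (j in (peak_idx + 1L):hi_bound) {
      if (env[j] < level) {
        right <- j - (level - env[j]) / (env[j - 1L] - env[j])
        break
      }
    }
  }
  right - left
}

#' Landmarks and parameters of a stance force envelope
#'
#' Detects the two principal peaks (the two highest local maxima of the
#' envelope smoothed with a short moving average, refined on the raw
#' envelope) and the valley between them, then computes the 15 envelope
#' parameters: peak-to-peak time distance; the heights of peak 1, peak 2
#' and the valley; the height difference between the peaks; the
#' peak-to-valley height ratios and their difference (peak1/valley minus
#' peak2/valley, capped at `ratio_cap` for vanishing valleys); the widths
#' of both peaks at 30% of their height and the width difference; and the
#' four slope rates (start to peak 1, peak 1 to valley, valley to peak 2,
#' peak 2 to stance end), each a height change per second.
#'
#' @param env Envelope force vector (N) of one stance.
#' @param sampling_rate Hz.
#' @param smooth_window Moving-average window (samples) used for peak
#'   detection; 1 disables smoothing.
#' @param ratio_cap Upper bound applied to the peak/valley ratios.
#' @return A list with `unimodal` (logical), `capped` (logical) and, when
#'   bimodal, the named 15-parameter numeric vector `params`.
#' @export
envelope_landmarks <- function(env, sampling_rate, smooth_window = 5,
                               ratio_cap = 50) {
  unimodal <- function() list(unimodal = TRUE, capped = FALSE, params = NULL)
  n <- length(env)
  if (n < 5) return(unimodal())
  sm <- moving_average(env, smooth_window)
  cand <- local_maxima(sm)
  if (length(cand) < 2) return(unimodal())
  ord <- cand[order(-sm[cand], cand)][1:2]
  half <- (smooth_window - 1L) %/% 2L
  p1 <- refine_index(env, min(ord), half, "max")
  p2 <- refine_index(env, max(ord), half, "max")
  if (p2 - p1 < 2) return(unimodal())
  v <- p1 + which.min(sm[p1:p2]) - 1L
  v <- refine_index(env, v, half, "min")
  v <- min(max(v, p1 + 1L), p2 - 1L)
  h1 <- env[p1]; h2 <- env[p2]; hv <- env[v]
  if (hv >= min(h1, h2)) return(unimodal())

  capped <- FALSE
  ratio <- function(h) {
    r <- if (hv > 0) h / hv else Inf
    if (r > ratio_cap) { capped <<- TRUE; ratio_cap } else r
  }
  r1 <- ratio(h1); r2 <- ratio(h2)
  fs <- sampling_rate
  slope <- function(i, j) {
    if (j == i) return(NA_real_)
    (env[j] - env[i]) / ((j - i) / fs)
  }
  params <- c(
    peak_distance = (p2 - p1) / fs,
    h_peak1 = h1, h_peak2 = h2, h_valley = hv,
    h_peak_diff = h1 - h2,
    ratio_p1_valley = r1, ratio_p2_valley = r2, ratio_diff = r1 - r2,
    width_peak1 = peak_width_samples(env, p1, 1L, v) / fs,
    width_peak2 = peak_width_samples(env, p2, v, n) / fs,
    width_diff = peak_width_samples(env, p1, 1L, v) / fs -
      peak_width_samples(env, p2, v, n) / fs,
    slope_start_p1 = slope(1L, p1),
    slope_p1_valley = slope(p1, v),
    slope_valley_p2 = slope(v, p2),
    slope_p2_end = slope(p2, n)
  )
  list(unimodal = FALSE, capped = capped, params = params,
       landmarks = c(peak1 = p1, valley = v, peak2 = p2))
}

wavelet_parameter_names <- function() {
  c("peak_distance", "h_peak1", "h_peak2", "h_valley", "h_peak_diff",
    "ratio_p1_valley", "ratio_p2_valley", "ratio_diff",
    "width_peak1", "width_peak2", "width_diff",
    "slope_start_p1", "slope_p1_valley", "slope_valley_p2", "slope_p2_end")
}

#' Envelope ("wavelet") feature block (30 features)
#'
#' Computes [envelope_landmarks()] for every left-foot stance and
#' aggregates each of the 15 parameters as the mean and standard
#' deviation over left stances. Stances with an undetectable valley
#' (unimodal envelopes) are excluded from aggregation and counted in the
#' attached QC attribute.
#'
#' @param recording Walking [insole_recording()] in N.
#' @param stances Trimmed stance tibble for the subject.
#' @param smooth_window,ratio_cap Passed to [envelope_landmarks()].
#' @return Named numeric vector of 30 features
#'   `wavelet.<parameter>.<mean_left|sd_left>`, with attribute `qc`
#'   (`n_left`, `n_unimodal`, `n_capped`).
#' @export
wavelet_features <- function(recording, stances, smooth_window = 5,
                             ratio_cap = 50) {
  left <- dplyr::filter(stances, .data$foot == "left")
  lms <- purrr::map(seq_len(nrow(left)), function(i) {
    env <- stance_envelope(recording, left$strike_idx[i], left$lift_idx[i],
                           "left")
    envelope_landmarks(env, recording_rate(recording), smooth_window,
                       ratio_cap)
  })
  ok <- !purrr::map_lgl(lms, "unimodal")
  mat <- if (any(ok)) {
    do.call(rbind, purrr::map(lms[ok], "params"))
  } else {
    matrix(numeric(), ncol = 15,
           dimnames = list(NULL, wavelet_parameter_names()))
  }
  out <- numeric(0)
  for (param in wavelet_parameter_names()) {
    v <- if (nrow(mat) > 0) mat[, param] else numeric(0)
    v <- v[is.finite(v)]
    res <- c(mean_left = if (length(v) > 0) mean(v) else NA_real_,
             sd_left = if (length(v) > 1) sd(v) else NA_real_)
    names(res) <- sprintf("wavelet.%s.%s", param, names(res))
    out <- c(out, res)
  }
  attr(out, "qc") <- tibble(
    n_left = nrow(left),
    n_unimodal = sum(!ok),
    n_capped = sum(purrr::map_lgl(lms, "capped"))
  )
  out
}
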