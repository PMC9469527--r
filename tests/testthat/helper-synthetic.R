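# shared fixture builders; everything is generated in code at test time

# a small default cohort, built once per test session and reused
.cohort_cache <- new.env(parent = emptyenv())

small_cohort <- function(n = 6, seed = 42, ...) {
  key <- paste0("c", n, "_", seed, "_", rlang::hash(list(...)))
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(
      generator_config(n_subjects = n, seed = seed, ...))
  }
  .cohort_cache[[key]]
}

# a bare force-channel recording in N with given left-foot channel matrix
# (right foot defaults to zeros); rows = samples
make_recording <- function(left, right = NULL, sampling_rate = 100,
                           units = "N", trial = "walking") {
  n <- nrow(left)
  if (is.null(right)) right <- matrix(0, n, 7)
  df <- tibble::tibble(time_s = (seq_len(n) - 1) / sampling_rate)
  for (k in 1:7) df[[paste0("L", k)]] <- left[, k]
  for (k in 1:7) df[[paste0("R", k)]] <- right[, k]
  insole_recording(df, sampling_rate, units, trial)
}

# stance tibble in the shape detect_walking_stances() produces
make_stances <- function(strike_idx, lift_idx, foot, segment = 1L,
                         sampling_rate = 100) {
  tibble::tibble(
    foot = foot, segment = segment,
    strike_idx = as.integer(strike_idx), lift_idx = as.integer(lift_idx),
    strike_s = (strike_idx - 1) / sampling_rate,
    lift_s = (lift_idx - 1) / sampling_rate,
    duration_s = (lift_idx - strike_idx) / sampling_rate
  )
}

# multiply all force channels of a recording by a constant
scale_recording <- function(recording, c) {
  ch <- c(paste0("L", 1:7), paste0("R", 1:7))
  out <- recording
  out[, ch] <- as.data.frame(as.matrix(recording[, ch]) * c)
  attr(out, "sampling_rate") <- attr(recording, "sampling_rate")
  attr(out, "units") <- attr(recording, "units")
  attr(out, "trial") <- attr(recording, "trial")
  out
}

# random feature table with independent labels for classifier null tests
null_feature_table <- function(n, p = 182, pos_fraction = 0.2, seed = 1) {
  withr::with_seed(seed, {
    x <- as.data.frame(matrix(rnorm(n * p), n))
    names(x) <- feature_names()[seq_len(p)]
    x$subject_id <- sprintf("N%03d", seq_len(n))
    n_pos <- round(pos_fraction * n)
    x$frail <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
    x$faller <- sample(rep(c(1L, 0L), c(n_pos, n - n_pos)))
    tibble::as_tibble(x)
  })
}

# nearest-event strike-time errors (detected vs ground truth), seconds
strike_errors <- function(cohort, stances) {
  purrr::map(unique(stances$subject_id), function(sid) {
    purrr::map(c("left", "right"), function(ft) {
      gt <- dplyr::filter(cohort$truth, .data$subject_id == sid,
                          .data$foot == ft)
      det <- dplyr::filter(stances, .data$subject_id == sid,
                           .data$foot == ft)
      purrr::map_dbl(det$strike_s, function(s) {
        s - gt$strike_s[which.min(abs(gt$strike_s - s))]
      })
    }) |> unlist()
  }) |> unlist()
}
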