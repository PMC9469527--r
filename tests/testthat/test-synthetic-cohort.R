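test_that("label counts follow deterministic rounding of the fractions", {
  co <- small_cohort(n = 100, seed = 1, frail_fraction = 0.285)
  expect_equal(sum(co$subjects$frail), round(0.285 * 100))
  expect_true(sum(co$subjects$frail) %in% 28:29)
  expect_equal(sum(co$subjects$faller), round(0.2 * 100))
  expect_setequal(unique(co$subjects$sex), c("female", "male"))
})

test_that("identical config and seed reproduce the cohort bitwise", {
  cfg <- generator_config(n_subjects = 3, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$subjects$walking[[2]], b$subjects$walking[[2]])
  expect_identical(a$subjects$standing[[3]], b$subjects$standing[[3]])
  c2 <- generate_cohort(generator_config(n_subjects = 3, seed = 12))
  expect_false(identical(a$subjects$walking[[1]], c2$subjects$walking[[1]]))
})

test_that("emitted pressures respect the sensor range and 10-bit grid", {
  co <- small_cohort(n = 3, seed = 5)
  for (i in 1:3) {
    for (trial in c("walking", "standing")) {
      m <- as.matrix(co$subjects[[trial]][[i]][, -1])
      expect_true(all(m >= 0 & m <= 550))
      steps <- m / (550 / 1023)
      expect_true(all(abs(steps - round(steps)) < 1e-9))
      # the 25 kPa response floor: no output between 0 and 25 kPa
      expect_true(all(m == 0 | m >= 25 - 550 / 1023))
    }
  }
})

test_that("noise-free stances have identical duration equal to the subject mean", {
  co <- generate_cohort(generator_config(
    n_subjects = 2, seed = 3, sensor_noise_sd = 0, stance_duration_cv = 0))
  for (i in 1:2) {
    sid <- co$subjects$subject_id[i]
    gt <- dplyr::filter(co$truth, subject_id == sid)
    dur <- round(gt$lift_s - gt$strike_s, 9)
    expect_equal(length(unique(dur)), 1)
    expect_equal(dur[1], co$subjects$params[[i]]$stance_duration,
                 tolerance = 0.5 / 100 / dur[1])
  }
})

test_that("stance timing: disjoint per foot, double support as configured", {
  co <- generate_cohort(generator_config(n_subjects = 2, seed = 9,
                                         double_support_fraction = 0.2))
  gt <- dplyr::filter(co$truth, subject_id == "S0001") |>
    dplyr::arrange(strike_s)
  for (ft in c("left", "right")) {
    g <- dplyr::filter(gt, foot == ft)
    expect_true(all(diff(g$strike_s) > 0))
    expect_true(all(g$strike_s[-1] >= g$lift_s[-nrow(g)]))  # disjoint
  }
  # consecutive opposite-foot stances overlap by ds/2 of the leading
  # stance's duration, within one sample
  for (i in seq_len(nrow(gt) - 1)) {
    if (gt$segment[i] != gt$segment[i + 1]) next
    expect_false(gt$foot[i] == gt$foot[i + 1])  # alternation
    ov <- gt$lift_s[i] - gt$strike_s[i + 1]
    dur <- gt$lift_s[i] - gt$strike_s[i]
    expect_equal(ov, 0.1 * dur, tolerance = 0.011 / ov)
  }
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(generator_config(n_subjects = 1), "n_subjects")
  expect_error(generator_config(frail_fraction = 1.2), "frail_fraction")
  expect_error(generator_config(sampling_rate = 0), "sampling_rate")
  expect_error(generator_config(stance_duration_mean = -1),
               "stance_duration_mean")
  expect_error(generator_config(sensor_noise_sd = -2), "sensor_noise_sd")
  expect_error(
    generator_config(effect_size_multipliers = list(frail = c(bogus = 2))),
    "stance_duration_mean")  # error lists the valid names
})

test_that("inject_group_effect with multiplier 1 leaves the cohort unchanged", {
  co <- small_cohort(n = 4, seed = 21)
  co2 <- inject_group_effect(co, "stance_duration_mean", 1.0)
  expect_equal(co2$truth, co$truth)
  expect_identical(co2$subjects$walking[[1]], co$subjects$walking[[1]])
})

test_that("injected stance-duration effect shifts realized group means ~30%", {
  co <- generate_cohort(generator_config(n_subjects = 40, seed = 2,
                                         frail_fraction = 0.5))
  co <- inject_group_effect(co, "stance_duration_mean", 1.3)
  gt <- dplyr::left_join(co$truth,
                         co$subjects[, c("subject_id", "frail")],
                         by = "subject_id")
  mean_dur <- gt |>
    dplyr::group_by(frail) |>
    dplyr::summarise(d = mean(lift_s - strike_s))
  ratio <- mean_dur$d[mean_dur$frail == 1] / mean_dur$d[mean_dur$frail == 0]
  expect_equal(ratio, 1.3, tolerance = 0.06)
})

test_that("peak/valley ratio injection shifts the extracted wavelet ratios", {
  co <- generate_cohort(generator_config(n_subjects = 30, seed = 4,
                                         frail_fraction = 0.5))
  co <- inject_group_effect(co, "peak_valley_ratio_mean", 0.7)
  feats <- extract_features(preprocess_cohort(co))
  p <- stats::wilcox.test(wavelet.ratio_p1_valley.mean_left ~ frail,
                          data = feats)$p.value
  expect_lt(p, 0.01)
})

test_that("unknown injected parameter errors with the valid names", {
  co <- small_cohort(n = 4, seed = 21)
  expect_error(inject_group_effect(co, "no_such_param", 2),
               "peak_valley_ratio_mean")
  expect_error(inject_group_effect(co, "stance_duration_mean", -1),
               "multiplier")
})
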