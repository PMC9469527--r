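test_that("peak/AUC parameters: constant and ramp stances match closed forms", {
  n <- 300
  left <- matrix(0, n, 7)
  left[100:170, 1] <- 50                              # constant 50 N
  left[100:170, 2] <- seq(0, 100, length.out = 71)    # linear ramp
  rec <- make_recording(left)
  st <- make_stances(100, 171, "left")
  tab <- peak_auc_stance_table(rec, st)
  const <- dplyr::filter(tab, sensor == 1)
  expect_equal(const$max_pressure, 50)
  expect_equal(const$t_max_rel, 0)          # plateau: first occurrence
  expect_equal(const$auc, 50, tolerance = 1e-9)  # constant x unit span
  ramp <- dplyr::filter(tab, sensor == 2)
  expect_equal(ramp$max_pressure, 100)
  expect_equal(ramp$t_max_rel, 1.0)
  expect_equal(ramp$auc, const$auc, tolerance = 1e-6)  # triangle = half
})

test_that("mirrored feet zero out every left-right difference feature", {
  # identical stance curves on both feet, staggered so every retained
  # stance has both support transitions
  dur <- 150L
  u <- (seq_len(dur) - 0.5) / dur
  curve <- vapply(1:7, function(k) {
    m <- 0.15 + 0.1 * k
    100 * exp(-(log(u / m))^2 / (2 * 0.3^2))
  }, numeric(dur))
  strikes <- seq(1, 701, by = 100)
  feet <- rep(c("right", "left"), length.out = length(strikes))
  n <- 900
  left <- matrix(0, n, 7); right <- matrix(0, n, 7)
  for (i in seq_along(strikes)) {
    rows <- strikes[i]:(strikes[i] + dur - 1)
    if (feet[i] == "left") left[rows, ] <- left[rows, ] + curve
    else right[rows, ] <- right[rows, ] + curve
  }
  rec <- make_recording(left, right)
  context <- make_stances(strikes, strikes + dur, feet)
  stances <- dplyr::filter(context, strike_idx >= 101, strike_idx <= 601)

  fv_peak <- peak_auc_features(rec, stances)
  fv_cop <- cop_1foot_features(rec, stances, sensor_layout(),
                               context = context)
  fv_gait <- gait_phase_features(stances, context = context)
  fv <- c(fv_peak, fv_cop, fv_gait)
  dict <- feature_dictionary()
  diff_feats <- dict$name[dict$aggregation == "diff_lr"]
  expect_equal(length(diff_feats), 36)  # 21 peak/AUC + 13 COP + 2 gait
  expect_equal(unname(fv[diff_feats]), rep(0, 36))
  expect_true(all(is.finite(fv[diff_feats])))
})

test_that("aggregation statistics match a brute-force recomputation", {
  co <- small_cohort(n = 2, seed = 23)
  prep <- preprocess_cohort(co)
  s <- prep$subjects
  tab <- peak_auc_stance_table(s$walking[[1]], s$stances[[1]])
  feats <- peak_auc_features(s$walking[[1]], s$stances[[1]])
  for (k in c(1, 4, 7)) {
    sub <- dplyr::filter(tab, sensor == k)
    vl <- sub$max_pressure[sub$foot == "left"]
    vr <- sub$max_pressure[sub$foot == "right"]
    expect_equal(unname(feats[sprintf("peak_auc.max_pressure.mean_left.s%d", k)]),
                 mean(vl), tolerance = 1e-12)
    expect_equal(unname(feats[sprintf("peak_auc.max_pressure.sd_left.s%d", k)]),
                 sd(vl), tolerance = 1e-12)
    expect_equal(unname(feats[sprintf("peak_auc.max_pressure.sd_both.s%d", k)]),
                 sd(sub$max_pressure), tolerance = 1e-12)
    expect_equal(unname(feats[sprintf("peak_auc.max_pressure.diff_lr.s%d", k)]),
                 mean(vl) - mean(vr), tolerance = 1e-12)
  }
})

test_that("single-foot COP parameters: straight path and support transitions", {
  co <- generate_cohort(generator_config(n_subjects = 2, seed = 29,
                                         sensor_noise_sd = 0))
  prep <- preprocess_cohort(co)
  s <- prep$subjects
  tab <- cop_1foot_stance_table(s$walking[[1]], s$stances[[1]], co$layout,
                                context = s$stances_all[[1]])
  expect_true(all(is.finite(tab$cpei)))
  expect_true(all(tab$cpei >= 0))
  expect_true(all(tab$min_y < tab$max_y))
  expect_equal(tab$range_y, tab$max_y - tab$min_y, tolerance = 1e-12)
  # transitions exist for every retained (interior) stance
  expect_true(all(is.finite(tab$x_d2s)))
  expect_true(all(is.finite(tab$x_s2d)))
  # the double-to-single transition happens early in stance: COP still
  # posterior of the single-to-double point
  expect_true(mean(tab$y_d2s) < mean(tab$y_s2d))
  # reference-level crossings: heel-to-toe paths cross both sensor levels
  expect_true(all(is.finite(tab$x_at_midfoot_y)))
  expect_true(all(is.finite(tab$x_at_forefoot_y)))
})

test_that("gait-phase parameters recover the generator's timing", {
  co <- generate_cohort(generator_config(
    n_subjects = 2, seed = 3, sensor_noise_sd = 0, stance_duration_cv = 0,
    double_support_fraction = 0.2))
  prep <- preprocess_cohort(co)
  s <- prep$subjects
  for (i in 1:2) {
    tab <- gait_phase_stance_table(s$stances[[i]], s$stances_all[[i]])
    expect_equal(unique(tab$duration_s),
                 round(co$subjects$params[[i]]$stance_duration * 100) / 100,
                 tolerance = 1e-9)
    expect_equal(mean(tab$double_support_pct), 20,
                 tolerance = 1.5 / 20)  # one sample per episode
  }
})

test_that("force features scale with force, time and ratio features do not", {
  co <- small_cohort(n = 2, seed = 23)
  prep <- preprocess_cohort(co)
  s <- prep$subjects
  fv1 <- extract_feature_vector(s$standing[[1]], s$walking[[1]],
                                s$stances[[1]], co$layout,
                                context = s$stances_all[[1]])
  fv2 <- extract_feature_vector(scale_recording(s$standing[[1]], 3),
                                scale_recording(s$walking[[1]], 3),
                                s$stances[[1]], co$layout,
                                context = s$stances_all[[1]])
  dict <- feature_dictionary()
  scale_of <- c(force = 3, force_rate = 3, power = 9)
  for (i in seq_len(nrow(dict))) {
    sc <- scale_of[dict$dimension[i]]
    if (is.na(sc)) sc <- 1
    a <- fv1[dict$name[i]]; b <- fv2[dict$name[i]]
    if (!is.finite(a) || abs(a) < 1e-9) next
    expect_equal(unname(b), unname(a * sc), tolerance = 1e-8,
                 label = dict$name[i])
  }
})
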