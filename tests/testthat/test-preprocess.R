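test_that("pressure-to-force conversion is linear with zero fixed", {
  m <- matrix(0, 200, 7)
  m[, 1] <- c(rep(100, 100), rep(0, 100))
  rec <- make_recording(m, units = "kPa")
  out <- convert_to_newtons(rec, sensor_area_cm2 = 1.0)
  expect_equal(recording_units(out), "N")
  expect_equal(out$L1[1], 10.0)           # 100 kPa x 1 cm2 = 10 N
  expect_equal(out$L1[150], 0)            # 0 maps to 0
  expect_equal(out$L2, rep(0, 200))
  out2 <- convert_to_newtons(scale_recording(rec, 2))
  expect_equal(as.matrix(out2[, -1]), as.matrix(out[, -1]) * 2)  # linearity
  out3 <- convert_to_newtons(rec, sensor_area_cm2 = 2.0)
  expect_equal(out3$L1[1], 20.0)
  expect_error(convert_to_newtons(scale_recording(rec, -1)), "negative")
  expect_error(convert_to_newtons(out), "already")
})

test_that("square-wave force yields exact stances; zero force yields none", {
  f <- rep(0, 400)
  for (s in c(50, 160, 270)) f[s:(s + 69)] <- 600
  st <- detect_stances(f, 100)
  expect_equal(nrow(st), 3)
  expect_equal(st$duration_s, rep(0.70, 3))
  expect_equal(st$strike_idx, c(50, 160, 270))
  expect_equal(st$lift_idx, c(120, 230, 340))
  expect_identical(st, detect_stances(f, 100))  # idempotent
  expect_equal(nrow(detect_stances(rep(0, 200), 100)), 0)
  expect_error(detect_stances(rep(0, 50), 100), "1 s")
})

test_that("hysteresis bridges short dips and rejects short contacts", {
  f <- rep(0, 400)
  f[100:199] <- 600
  f[150:152] <- 0         # 30 ms drop-out, shorter than min_swing: bridged
  st <- detect_stances(f, 100)
  expect_equal(nrow(st), 1)
  expect_equal(st$duration_s, 1.0)
  f2 <- rep(0, 400)
  f2[100:104] <- 600      # 50 ms blip < min_contact: rejected
  f2[200:299] <- 600
  st2 <- detect_stances(f2, 100)
  expect_equal(nrow(st2), 1)
  expect_equal(st2$strike_idx, 200)
})

test_that("transient-step trimming keeps the middle stances per segment", {
  st <- make_stances(seq(100, 800, by = 100), seq(170, 870, by = 100),
                     rep(c("left", "right"), 4))
  out <- trim_transient_steps(st, k = 2)
  expect_equal(nrow(out), 4)
  expect_equal(out$strike_idx, c(300, 400, 500, 600))
  out5 <- trim_transient_steps(st[1:5, ], k = 2)
  expect_equal(nrow(out5), 1)
  expect_equal(out5$strike_idx, 300)
  expect_warning(out4 <- trim_transient_steps(st[1:4, ], k = 2), "removed")
  expect_equal(nrow(out4), 0)
  # segments are trimmed independently
  st2 <- dplyr::bind_rows(st, dplyr::mutate(st, segment = 2L,
                                            strike_idx = strike_idx + 2000L,
                                            lift_idx = lift_idx + 2000L,
                                            strike_s = strike_s + 20,
                                            lift_s = lift_s + 20))
  expect_equal(nrow(trim_transient_steps(st2, k = 2)), 8)
})

test_that("inclusion rule keeps >=3 steps per foot and logs exclusions", {
  st <- dplyr::bind_rows(
    make_stances(c(100, 200, 300), c(170, 270, 370), rep("left", 3)) |>
      dplyr::mutate(subject_id = "A"),
    make_stances(c(150, 250, 350), c(220, 320, 420), rep("right", 3)) |>
      dplyr::mutate(subject_id = "A"),
    make_stances(seq(100, 500, 100), seq(170, 570, 100), rep("left", 5)) |>
      dplyr::mutate(subject_id = "B"),
    make_stances(c(150, 250), c(220, 320), rep("right", 2)) |>
      dplyr::mutate(subject_id = "B")
  )
  res <- apply_inclusion_rule(st, c("A", "B", "C"))
  expect_setequal(unique(res$stances$subject_id), "A")   # boundary: 3/3 kept
  expect_setequal(res$exclusions$subject_id, c("B", "C"))
  expect_match(res$exclusions$reason[res$exclusions$subject_id == "B"],
               "left: 5, right: 2")
})

test_that("standing window keeps exactly the last 45 s", {
  co <- small_cohort(n = 2, seed = 13)
  rec <- co$subjects$standing[[1]]
  win <- standing_window(rec)
  expect_equal(nrow(win), 4500)
  expect_equal(as.matrix(win[, -1]),
               as.matrix(rec[(nrow(rec) - 4499):nrow(rec), -1]))
  exact <- insolegait:::reslice_recording(rec, 1:4500)
  expect_equal(nrow(standing_window(exact)), 4500)  # 45 s in, unchanged
  short <- insolegait:::reslice_recording(rec, 1:3000)
  expect_error(standing_window(short), "30.00 s")
})

test_that("sum of 14 channels equals left + right foot totals everywhere", {
  co <- small_cohort(n = 2, seed = 13)
  rec <- co$subjects$walking[[1]]
  total14 <- rowSums(as.matrix(rec[, -1]))
  expect_equal(total14,
               insolegait:::foot_total(rec, "left") +
                 insolegait:::foot_total(rec, "right"))
})

test_that("detected events recover generator ground truth on a small cohort", {
  co <- small_cohort(n = 5, seed = 7)
  prep <- preprocess_cohort(co)
  expect_equal(nrow(prep$exclusions), 0)
  errs <- strike_errors(co, prep$stances)
  expect_gte(mean(abs(errs) <= 0.020), 0.95)
  # idempotence at the cohort level
  prep2 <- preprocess_cohort(co)
  expect_identical(prep$stances, prep2$stances)
})
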