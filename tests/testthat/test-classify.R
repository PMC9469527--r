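test_that("balanced accuracy and weighted F1 behave on known matrices", {
  # always-majority classifier on an imbalanced problem: 0.5 by definition
  cm <- confusion_matrix(truth = rep(c(0, 1), c(80, 20)), pred = rep(0, 100))
  expect_equal(balanced_accuracy(cm), 0.5)
  # hand-computed small case
  cm <- matrix(c(6, 2, 1, 3), 2, byrow = TRUE,
               dimnames = list(c("0", "1"), c("0", "1")))
  # class 0: prec 6/7, rec 6/8, f1 = 2*(6/7)*(6/8)/((6/7)+(6/8)) = 0.8
  # class 1: prec 3/5, rec 3/4, f1 = 2/3
  expect_equal(balanced_accuracy(cm), mean(c(6 / 8, 3 / 4)))
  expect_equal(weighted_f1(cm), (8 * 0.8 + 4 * (2 / 3)) / 12)
  # perfect prediction
  cm <- confusion_matrix(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(balanced_accuracy(cm), 1)
  expect_equal(weighted_f1(cm), 1)
})

test_that("each tree trains on a class-balanced bootstrap", {
  d <- null_feature_table(60, p = 10, pos_fraction = 1 / 3)
  fit <- fit_balanced_forest(d, "frail", n_trees = 25, seed = 1,
                             keep_inbag = TRUE)
  y <- factor(d$frail, levels = c("0", "1"))
  m <- min(table(y))
  inbag <- fit$inbag  # subjects x trees count matrix
  per_class <- rowsum(inbag, y)
  expect_true(all(per_class["0", ] == m))
  expect_true(all(per_class["1", ] == m))
})

test_that("a single-class training set is rejected", {
  d <- null_feature_table(20, p = 5)
  d$frail <- 1L
  expect_error(fit_balanced_forest(d, "frail"), "single class")
})

test_that("a perfectly separating feature is learned", {
  d <- null_feature_table(60, p = 10, pos_fraction = 1 / 3, seed = 5)
  f1 <- feature_names()[1]
  d[[f1]] <- withr::with_seed(6, ifelse(d$frail == 1, rnorm(60, 8),
                                        rnorm(60, -8)))
  rep <- cross_validate(d, "frail", n_repeats = 3, n_trees = 200, seed = 2)
  expect_gte(rep$summary$balanced_accuracy_mean, 0.98)
})

test_that("every subject is validated exactly once per repeat", {
  d <- null_feature_table(25, p = 8, pos_fraction = 0.4, seed = 3)
  rep <- cross_validate(d, "frail", n_repeats = 2, n_trees = 30, seed = 7)
  totals <- rep$per_fold |>
    dplyr::group_by(rep) |>
    dplyr::summarise(n = sum(tn + fp + fn + tp))
  expect_equal(totals$n, c(25, 25))
})

test_that("reported metrics agree with the stored fold confusion matrices", {
  d <- null_feature_table(40, p = 10, pos_fraction = 0.3, seed = 11)
  rep <- cross_validate(d, "frail", n_repeats = 2, n_trees = 50, seed = 4)
  recomputed <- purrr::map_dbl(seq_len(nrow(rep$per_fold)), function(i) {
    r <- rep$per_fold[i, ]
    cm <- matrix(c(r$tn, r$fp, r$fn, r$tp), 2, byrow = TRUE)
    balanced_accuracy(cm)
  })
  expect_equal(rep$per_fold$balanced_accuracy, recomputed, tolerance = 1e-12)
  expect_equal(rep$summary$balanced_accuracy_mean,
               mean(rep$per_repeat$balanced_accuracy), tolerance = 1e-12)
  expect_equal(rowSums(rep$confusion_norm), c("0" = 1, "1" = 1),
               tolerance = 1e-9)
})

test_that("cross-validation is deterministic under a fixed seed", {
  d <- null_feature_table(30, p = 8, pos_fraction = 0.4, seed = 13)
  a <- cross_validate(d, "frail", n_repeats = 2, n_trees = 30, seed = 5)
  b <- cross_validate(d, "frail", n_repeats = 2, n_trees = 30, seed = 5)
  expect_identical(a$per_fold, b$per_fold)
  c2 <- cross_validate(d, "frail", n_repeats = 2, n_trees = 30, seed = 6)
  expect_false(identical(a$per_fold, c2$per_fold))
})

test_that("undersized classes are rejected with a clear message", {
  d <- null_feature_table(12, p = 5, pos_fraction = 0.25, seed = 1)
  expect_error(cross_validate(d, "frail", n_folds = 5), "n_folds")
})

test_that("an informative feature earns mean rank 1; a duplicate shares it", {
  d <- null_feature_table(80, p = 182, pos_fraction = 0.25, seed = 21)
  f1 <- feature_names()[50]
  d[[f1]] <- withr::with_seed(22, ifelse(d$frail == 1, rnorm(80, 6),
                                         rnorm(80, -6)))
  imp <- importance_ranking(d, "frail", n_repeats = 5, n_trees = 100,
                            seed = 3)
  expect_equal(imp$ranking$feature[1], f1)
  expect_equal(imp$ranking$mean_rank[1], 1)
  expect_true(f1 %in% imp$top)
  # duplicate the signal: both copies occupy the two leading ranks
  f2 <- feature_names()[120]
  d[[f2]] <- d[[f1]]
  imp2 <- importance_ranking(d, "frail", n_repeats = 5, n_trees = 100,
                             seed = 3)
  expect_setequal(imp2$ranking$feature[1:2], c(f1, f2))
  expect_lte(max(imp2$ranking$mean_rank[1:2]), 2.5)
})

test_that("pure-noise problems produce no persistent top-ranked feature", {
  ranks <- purrr::map_int(1:3, function(s) {
    d <- null_feature_table(40, p = 30, pos_fraction = 0.3, seed = 30 + s)
    imp <- importance_ranking(d, "frail", n_repeats = 2, n_trees = 50,
                              seed = s)
    which(imp$ranking$feature == feature_names()[1])
  })
  expect_gt(max(ranks), 1)  # never the same fixed feature on top everywhere
})

test_that("subgroup models follow the published table layout", {
  d <- null_feature_table(120, p = 10, pos_fraction = 0.3, seed = 17)
  withr::with_seed(1, {
    d$age <- sample(60:90, 120, replace = TRUE)
    d$sex <- sample(c("female", "male"), 120, replace = TRUE)
  })
  mods <- subgroup_models(d, n_repeats = 1, n_trees = 20, seed = 9)
  expect_equal(sum(mods$target == "frail"), 7)
  expect_equal(sum(mods$target == "faller"), 9)
  expect_true(all(c("frail", "non_frail") %in%
                    mods$subgroup[mods$target == "faller"]))
  # age bands partition the >= 65 total
  n65 <- mods$n[mods$target == "frail" & mods$subgroup == "age_65_plus"]
  bands <- mods$n[mods$target == "frail" &
                    mods$subgroup %in% c("age_65_69", "age_70_74",
                                         "age_75_plus")]
  expect_equal(sum(bands), n65)
  # an empty subgroup is skipped with a logged reason
  d2 <- dplyr::mutate(d, sex = "female")
  mods2 <- subgroup_models(d2, targets = "frail", n_repeats = 1,
                           n_trees = 20, seed = 9)
  men <- dplyr::filter(mods2, subgroup == "men_65_plus")
  expect_true(men$skipped)
  expect_match(men$reason, "below n_folds")
})

test_that("tidy and glance expose per-repeat metrics and the summary", {
  d <- null_feature_table(30, p = 8, pos_fraction = 0.4, seed = 13)
  rep <- cross_validate(d, "frail", n_repeats = 2, n_trees = 30, seed = 5)
  td <- generics::tidy(rep)
  expect_equal(nrow(td), 2)
  expect_true(all(c("balanced_accuracy", "weighted_f1") %in% names(td)))
  gl <- generics::glance(rep)
  expect_equal(gl$n, 30)
  imp <- importance_ranking(d, "frail", n_repeats = 2, n_trees = 20,
                            seed = 1)
  expect_equal(nrow(generics::tidy(imp)), 8)
  p1 <- ggplot2::autoplot(rep)
  p2 <- ggplot2::autoplot(imp)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
})

test_that("balanced accuracy responds monotonically to the injected effect", {
  base <- generate_cohort(generator_config(n_subjects = 60, seed = 37,
                                           frail_fraction = 0.3))
  ba <- purrr::map_dbl(c(1.0, 1.2, 1.4), function(mult) {
    co <- if (mult == 1) base else
      inject_group_effect(base, "stance_duration_mean", mult)
    feats <- impute_features(extract_features(preprocess_cohort(co)))
    cross_validate(feats, "frail", n_repeats = 5,
                   seed = 41)$summary$balanced_accuracy_mean
  })
  # never decreases beyond Monte-Carlo noise along the effect grid
  expect_true(all(diff(ba) > -0.07))
  expect_gt(ba[3], ba[1])
})
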