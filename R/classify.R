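# --- metrics --------------------------------------------------------------

#' Confusion matrix and derived metrics
#'
#' `confusion_matrix()` returns a 2x2 count matrix with true classes in
#' rows and predicted classes in columns (levels `0`, `1`).
#' `balanced_accuracy()` is the unweighted mean of per-class recalls (0.5
#' for a trivial always-one-class classifier). `weighted_f1()` averages
#' per-class F1 scores weighted by true class frequency.
#'
#' @param truth,pred Vectors of 0/1 labels (or factors with those levels).
#' @param cm A 2x2 confusion count matrix (rows = truth).
#' @return `confusion_matrix()`: matrix; the metrics: a scalar in `[0,1]`.
#' @export
confusion_matrix <- function(truth, pred) {
  lv <- c("0", "1")
  table(truth = factor(truth, levels = lv),
        pred = factor(pred, levels = lv))
}

#' @rdname confusion_matrix
#' @export
balanced_accuracy <- function(cm) {
  rs <- rowSums(cm)
  mean(diag(cm)[rs > 0] / rs[rs > 0])
}

#' @rdname confusion_matrix
#' @export
weighted_f1 <- function(cm) {
  n <- sum(cm)
  f1s <- purrr::map_dbl(seq_len(nrow(cm)), function(i) {
    tp <- cm[i, i]
    prec <- if (sum(cm[, i]) > 0) tp / sum(cm[, i]) else 0
    rec <- if (sum(cm[i, ]) > 0) tp / sum(cm[i, ]) else 0
    if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  })
  sum(f1s * rowSums(cm) / n)
}

# --- balanced random forest ------------------------------------------------

default_feature_columns <- function(data) {
  cols <- intersect(feature_names(), names(data))
  if (length(cols) == 0) {
    cols <- setdiff(names(data)[purrr::map_lgl(data, is.numeric)],
                    c("age", "frail", "faller"))
  }
  cols
}

#' Fit a balanced random forest
#'
#' A forest of `n_trees` trees in which every tree is grown on a
#' class-balanced bootstrap: a with-replacement sample of minority-class
#' size from each class (majority class down-sampled per tree). Trees are
#' grown to purity (no depth cap, terminal nodes of size 1) with the Gini
#' split criterion and `floor(sqrt(p))` candidate features per split;
#' prediction is by majority vote.
#'
#' @param data Data frame holding the target column and feature columns.
#' @param target Name of the 0/1 target column.
#' @param feature_cols Feature column names (default: the 182 extracted
#'   features present in `data`).
#' @param n_trees Number of trees.
#' @param mtry Features tried per split (default `floor(sqrt(p))`).
#' @param seed Optional seed set before fitting.
#' @param keep_inbag Keep the per-tree in-bag counts (for audit).
#' @return A `randomForest` fit.
#' @export
fit_balanced_forest <- function(data, target, feature_cols = NULL,
                                n_trees = 200, mtry = NULL, seed = NULL,
                                keep_inbag = FALSE) {
  if (is.null(feature_cols)) feature_cols <- default_feature_columns(data)
  y <- factor(data[[target]], levels = c("0", "1"))
  if (length(unique(y)) < 2) {
    abort_data("training data contain a single class")
  }
  x <- as.data.frame(data[, feature_cols])
  if (anyNA(x)) abort_data("feature matrix contains NA; impute first")
  if (is.null(mtry)) mtry <- floor(sqrt(ncol(x)))
  m <- min(table(y))
  fit_fun <- function() {
    randomForest::randomForest(
      x = x, y = droplevels(y), ntree = n_trees, mtry = mtry,
      replace = TRUE, strata = droplevels(y), sampsize = c(m, m),
      nodesize = 1, keep.inbag = keep_inbag)
  }
  if (!is.null(seed)) withr::with_seed(seed, fit_fun()) else fit_fun()
}

# median imputation learned on the training fold, applied to both folds
fold_impute <- function(train, test, cols) {
  for (cl in cols) {
    med <- median(train[[cl]][is.finite(train[[cl]])])
    if (!is.finite(med)) med <- 0
    train[[cl]][!is.finite(train[[cl]])] <- med
    test[[cl]][!is.finite(test[[cl]])] <- med
  }
  list(train = train, test = test)
}

stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    fold[idx] <- rep(seq_len(n_folds), length.out = length(idx))
  }
  fold
}

#' Repeated stratified cross-validation of the balanced forest
#'
#' Per repeat the data are split into `n_folds` stratified folds; each
#' fold serves once as validation for a forest trained on the remaining
#' folds. Balanced accuracy and weighted F1 are averaged over the folds
#' of a repeat, then summarised as mean and SD over repeats. Validation
#' confusion matrices are pooled over all folds and repeats and reported
#' both as counts and row-normalised (per-true-class percentages).
#'
#' @inheritParams fit_balanced_forest
#' @param n_folds Number of CV folds.
#' @param n_repeats Number of independent repeats (fresh splits).
#' @param seed Master seed; per-repeat seeds are spawned from it and
#'   recorded in the report.
#' @return Object of class `insole_cv_report`: list with `summary`
#'   (one-row tibble), `per_repeat`, `per_fold`, `confusion` (counts),
#'   `confusion_norm`, `spec` and `repeat_seeds`.
#' @export
cross_validate <- function(data, target, feature_cols = NULL, n_folds = 5,
                           n_repeats = 100, n_trees = 200, mtry = NULL,
                           seed = 1L) {
  if (is.null(feature_cols)) feature_cols <- default_feature_columns(data)
  y <- factor(data[[target]], levels = c("0", "1"))
  if (anyNA(y)) abort_data("target column contains NA")
  if (min(table(y)) < n_folds) {
    abort_data(sprintf(
      "each class needs at least n_folds = %d subjects (have %d/%d)",
      n_folds, sum(y == "0"), sum(y == "1")))
  }
  repeat_seeds <- withr::with_seed(seed,
                                   sample.int(.Machine$integer.max - 1L,
                                              n_repeats))
  pooled <- matrix(0, 2, 2, dimnames = list(truth = c("0", "1"),
                                            pred = c("0", "1")))
  per_fold <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    per_fold[[r]] <- withr::with_seed(repeat_seeds[r], {
      fold <- stratified_folds(y, n_folds)
      purrr::map(seq_len(n_folds), function(k) {
        fi <- fold_impute(data[fold != k, , drop = FALSE],
                          data[fold == k, , drop = FALSE], feature_cols)
        fit <- fit_balanced_forest(fi$train, target, feature_cols,
                                   n_trees, mtry)
        pred <- stats::predict(fit, as.data.frame(fi$test[, feature_cols]))
        cm <- confusion_matrix(fi$test[[target]], pred)
        tibble(rep = r, fold = k,
               balanced_accuracy = balanced_accuracy(cm),
               weighted_f1 = weighted_f1(cm),
               tn = cm[1, 1], fp = cm[1, 2], fn = cm[2, 1], tp = cm[2, 2])
      }) |> list_rbind()
    })
  }
  per_fold <- list_rbind(per_fold)
  pooled[1, 1] <- sum(per_fold$tn); pooled[1, 2] <- sum(per_fold$fp)
  pooled[2, 1] <- sum(per_fold$fn); pooled[2, 2] <- sum(per_fold$tp)
  per_repeat <- per_fold |>
    dplyr::group_by(rep) |>
    dplyr::summarise(
      balanced_accuracy = mean(.data$balanced_accuracy),
      weighted_f1 = mean(.data$weighted_f1), .groups = "drop")
  summary <- tibble(
    target = target, n = length(y), n_positive = sum(y == "1"),
    n_folds = n_folds, n_repeats = n_repeats, n_trees = n_trees,
    balanced_accuracy_mean = mean(per_repeat$balanced_accuracy),
    balanced_accuracy_sd = sd(per_repeat$balanced_accuracy),
    weighted_f1_mean = mean(per_repeat$weighted_f1),
    weighted_f1_sd = sd(per_repeat$weighted_f1))
  structure(list(
    summary = summary, per_repeat = per_repeat, per_fold = per_fold,
    confusion = pooled, confusion_norm = pooled / rowSums(pooled),
    spec = list(target = target, n_folds = n_folds, n_repeats = n_repeats,
                n_trees = n_trees, seed = seed,
                feature_cols = feature_cols),
    repeat_seeds = repeat_seeds), class = "insole_cv_report")
}

#' @export
print.insole_cv_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<balanced random forest CV: target %s, n = %d (%d positive)\n",
           " balanced accuracy %.3f +/- %.3f, weighted F1 %.3f +/- %.3f\n",
           " over %d repeats of stratified %d-fold CV, %d trees>\n"),
    s$target, s$n, s$n_positive, s$balanced_accuracy_mean,
    s$balanced_accuracy_sd, s$weighted_f1_mean, s$weighted_f1_sd,
    s$n_repeats, s$n_folds, s$n_trees))
  invisible(x)
}

# --- feature importance ----------------------------------------------------

#' Impurity-based feature importance ranking
#'
#' Per repeat a balanced forest is fitted on the full data (fresh seed per
#' repeat); the mean decrease in Gini impurity gives each feature a rank
#' (1 = most important, ties broken by feature order). Ranks are averaged
#' across repeats.
#'
#' @inheritParams cross_validate
#' @param top_k How many leading features the `top` element reports.
#' @return Object of class `insole_importance`: list with `ranking`
#'   (tibble `feature`, `mean_rank`, `mean_importance`, sorted), `top`,
#'   and the spec.
#' @export
importance_ranking <- function(data, target, feature_cols = NULL,
                               n_repeats = 100, n_trees = 200, mtry = NULL,
                               seed = 1L, top_k = 10) {
  if (is.null(feature_cols)) feature_cols <- default_feature_columns(data)
  data <- impute_features(data, feature_cols)
  repeat_seeds <- withr::with_seed(seed,
                                   sample.int(.Machine$integer.max - 1L,
                                              n_repeats))
  p <- length(feature_cols)
  ranks <- matrix(NA_real_, n_repeats, p)
  imps <- matrix(NA_real_, n_repeats, p)
  for (r in seq_len(n_repeats)) {
    fit <- fit_balanced_forest(data, target, feature_cols, n_trees, mtry,
                               seed = repeat_seeds[r])
    imp <- fit$importance[, "MeanDecreaseGini"]
    imps[r, ] <- imp
    ranks[r, ] <- rank(-imp, ties.method = "first")
  }
  ranking <- tibble(
    feature = feature_cols,
    mean_rank = colMeans(ranks),
    mean_importance = colMeans(imps)
  ) |> dplyr::arrange(.data$mean_rank)
  structure(list(ranking = ranking,
                 top = ranking$feature[seq_len(min(top_k, p))],
                 spec = list(target = target, n_repeats = n_repeats,
                             n_trees = n_trees, seed = seed)),
            class = "insole_importance")
}

#' @export
print.insole_importance <- function(x, ...) {
  cat(sprintf("<impurity importance ranking: target %s, %d repeats>\n",
              x$spec$target, x$spec$n_repeats))
  print(utils::head(x$ranking, 10))
  invisible(x)
}

# --- subgroup models -------------------------------------------------------

subgroup_definitions <- function() {
  tibble(
    subgroup = c("whole_population", "age_65_plus", "age_65_69",
                 "age_70_74", "age_75_plus", "women_65_plus",
                 "men_65_plus", "frail", "non_frail"),
    filter = list(
      function(d) rep(TRUE, nrow(d)),
      function(d) d$age >= 65,
      function(d) d$age >= 65 & d$age <= 69,
      function(d) d$age >= 70 & d$age <= 74,
      function(d) d$age >= 75,
      function(d) d$sex == "female" & d$age >= 65,
      function(d) d$sex == "male" & d$age >= 65,
      function(d) d$frail == 1,
      function(d) d$frail == 0
    )
  )
}

#' Fit the whole-population and subgroup models
#'
#' Builds one cross-validated model per (target x subgroup) combination:
#' for the frailty target the whole population plus the age (>= 65,
#' 65-69, 70-74, >= 75) and sex (women / men >= 65) subgroups (7 models);
#' for the fall-history target additionally the frail-only and
#' non-frail-only subgroups (9 models). Subgroups with fewer than
#' `n_folds` subjects in either class are skipped with a logged reason.
#'
#' @inheritParams cross_validate
#' @param targets Targets to model (subset of `"frail"`, `"faller"`).
#' @return Tibble with `target`, `subgroup`, `n`, `n_positive`,
#'   `skipped`, `reason`, metric summaries and a `report` list-column of
#'   [cross_validate()] results.
#' @export
subgroup_models <- function(data, targets = c("frail", "faller"),
                            feature_cols = NULL, n_folds = 5,
                            n_repeats = 100, n_trees = 200, seed = 1L) {
  defs <- subgroup_definitions()
  plan <- list_rbind(purrr::map(targets, function(tg) {
    keep <- if (tg == "frail") {
      defs$subgroup[!defs$subgroup %in% c("frail", "non_frail")]
    } else {
      defs$subgroup
    }
    dplyr::mutate(dplyr::filter(defs, .data$subgroup %in% keep), target = tg)
  }))
  purrr::map(seq_len(nrow(plan)), function(i) {
    tg <- plan$target[i]
    sg <- plan$subgroup[i]
    sub <- data[plan$filter[[i]](data), , drop = FALSE]
    tab <- table(factor(sub[[tg]], levels = c("0", "1")))
    base <- tibble(target = tg, subgroup = sg, n = nrow(sub),
                   n_positive = unname(tab["1"]))
    if (any(tab < n_folds)) {
      return(dplyr::mutate(
        base, skipped = TRUE,
        reason = sprintf("class counts %d/%d below n_folds = %d",
                         tab["0"], tab["1"], n_folds),
        balanced_accuracy_mean = NA_real_, balanced_accuracy_sd = NA_real_,
        weighted_f1_mean = NA_real_, weighted_f1_sd = NA_real_,
        report = list(NULL)))
    }
    rep <- cross_validate(sub, tg, feature_cols, n_folds, n_repeats,
                          n_trees, seed = seed + i)
    dplyr::mutate(
      base, skipped = FALSE, reason = NA_character_,
      balanced_accuracy_mean = rep$summary$balanced_accuracy_mean,
      balanced_accuracy_sd = rep$summary$balanced_accuracy_sd,
      weighted_f1_mean = rep$summary$weighted_f1_mean,
      weighted_f1_sd = rep$summary$weighted_f1_sd,
      report = list(rep))
  }) |> list_rbind()
}
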