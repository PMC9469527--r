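# --- broom-style accessors -------------------------------------------------

#' Tidy a cross-validation report
#'
#' @param x An `insole_cv_report`.
#' @param ... Unused.
#' @return One row per repeat with `rep`, `balanced_accuracy`,
#'   `weighted_f1`.
#' @export
tidy.insole_cv_report <- function(x, ...) x$per_repeat

#' One-row summary of a cross-validation report
#'
#' @param x An `insole_cv_report`.
#' @param ... Unused.
#' @return One-row tibble with counts and metric means/SDs.
#' @export
glance.insole_cv_report <- function(x, ...) x$summary

#' Tidy an importance ranking
#'
#' @param x An `insole_importance`.
#' @param ... Unused.
#' @return Tibble `feature`, `mean_rank`, `mean_importance`.
#' @export
tidy.insole_importance <- function(x, ...) x$ranking

#' @export
glance.insole_importance <- function(x, ...) {
  tibble(target = x$spec$target, n_repeats = x$spec$n_repeats,
         n_trees = x$spec$n_trees, top_feature = x$ranking$feature[1])
}

# --- plots -----------------------------------------------------------------

#' Plot a pooled confusion matrix
#'
#' Row-normalised pooled validation confusion matrix as a shaded tile
#' plot (percentages of each true class).
#'
#' @param object An `insole_cv_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.insole_cv_report <- function(object, ...) {
  cm <- object$confusion_norm
  df <- tibble(
    truth = rep(rownames(cm), times = 2),
    pred = rep(colnames(cm), each = 2),
    share = as.numeric(cm)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$truth,
                                   fill = .data$share)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%",
                                                    100 * .data$share))) +
    ggplot2::scale_y_discrete(limits = rev(rownames(cm))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "predicted class", y = "true class",
                  fill = "row share",
                  title = sprintf("%s: balanced accuracy %.2f ± %.2f",
                                  object$summary$target,
                                  object$summary$balanced_accuracy_mean,
                                  object$summary$balanced_accuracy_sd))
}

#' Plot the leading features of an importance ranking
#'
#' @param object An `insole_importance`.
#' @param top_k Number of features shown.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.insole_importance <- function(object, top_k = 10, ...) {
  df <- utils::head(object$ranking, top_k)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_rank,
    y = stats::reorder(.data$feature, -.data$mean_rank))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean rank across repeats (1 = most important)",
                  y = NULL, title = "impurity-based feature importance")
}

#' Plot the sensor curves and force envelope of one stance
#'
#' @param recording Walking [insole_recording()] in N.
#' @param stance One-row stance tibble (`strike_idx`, `lift_idx`, `foot`).
#' @return A ggplot of the 7 sensor forces and their envelope.
#' @export
plot_stance_envelope <- function(recording, stance) {
  fs <- recording_rate(recording)
  m <- stance_forces(recording, stance$strike_idx, stance$lift_idx,
                     stance$foot)
  env <- row_max(m)
  t <- (seq_len(nrow(m)) - 1) / fs
  long <- as_tibble(m) |>
    dplyr::mutate(time_s = t) |>
    tidyr::pivot_longer(-"time_s", names_to = "sensor",
                        values_to = "force_n")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$force_n,
                                     colour = .data$sensor)) +
    ggplot2::geom_line() +
    ggplot2::geom_line(data = tibble(time_s = t, force_n = env),
                       ggplot2::aes(.data$time_s, .data$force_n),
                       colour = "black", linewidth = 1,
                       inherit.aes = FALSE) +
    ggplot2::labs(x = "time in stance (s)", y = "force (N)",
                  title = sprintf("%s-foot stance envelope", stance$foot))
}

#' Plot a COP excursion path
#'
#' @param path Tibble with `x_mm`, `y_mm` (e.g. from [cop_path()]).
#' @return A ggplot of the trajectory.
#' @export
plot_cop_path <- function(path) {
  ggplot2::ggplot(dplyr::filter(path, is.finite(.data$x_mm)),
                  ggplot2::aes(.data$x_mm, .data$y_mm)) +
    ggplot2::geom_path(alpha = 0.7) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "medial-lateral x (mm)",
                  y = "anterior-posterior y (mm)",
                  title = "COP excursion trajectory")
}
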