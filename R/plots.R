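#' Plot a learning curve
#'
#' Mean F-score (with precision and recall) against training-set size,
#' with one-standard-deviation ribbons across folds. The x axis is
#' logarithmic: learning curves are read in decades of annotation effort.
#'
#' @param object an `ade_learning_curve` from [learning_curve()].
#' @param metrics which metrics to draw (any of `"precision"`,
#'   `"recall"`, `"f_score"`).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ade_learning_curve <- function(object,
                                        metrics = c("precision", "recall",
                                                    "f_score"),
                                        ...) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  long <- tibble(
    n_docs = rep(object$n_docs, 3L),
    metric = rep(c("precision", "recall", "f_score"),
                 each = nrow(object)),
    mean = c(object$precision_mean, object$recall_mean, object$f_mean),
    sd = c(object$precision_sd, object$recall_sd, object$f_sd)
  ) |>
    filter(.data$metric %in% metrics)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_docs, y = .data$mean,
                                     colour = .data$metric,
                                     fill = .data$metric)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean - .data$sd, 0),
                                      ymax = pmin(.data$mean + .data$sd, 1)),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "training documents", y = "score",
                  title = "Relation extraction learning curve",
                  subtitle = "mean ± SD across cross-validation folds") +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation results
#'
#' Per-fold precision, recall and F as points, with the pooled
#' (micro-averaged) value as a horizontal line per metric.
#'
#' @param object an `ade_cv` from [cross_validate()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.ade_cv <- function(object, ...) {
  folds <- tidy(object)
  long <- tibble(
    fold = rep(folds$fold, 3L),
    metric = rep(c("precision", "recall", "f_score"), each = nrow(folds)),
    value = c(folds$precision, folds$recall, folds$f_score)
  )
  pooled <- tibble(
    metric = c("precision", "recall", "f_score"),
    value = c(object$pooled$precision, object$pooled$recall,
              object$pooled$f_score)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.6) +
    ggplot2::geom_crossbar(data = pooled,
                           ggplot2::aes(ymin = .data$value,
                                        ymax = .data$value),
                           width = 0.4, colour = "firebrick") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "score over TRUE relations",
                  title = sprintf("%d-fold document-level cross-validation",
                                  object$k),
                  subtitle = "points: folds; bar: pooled") +
    ggplot2::theme_minimal()
}

#' Plot the most influential kernel features of a trained model
#'
#' @param model an `ade_model`.
#' @param n number of features per direction (default 15).
#' @return A ggplot object: signed weights of the top features, coloured
#'   by sub-kernel namespace.
#' @export
plot_model_weights <- function(model, n = 15L) {
  tw <- tidy(model)
  top <- bind_rows(head(filter(tw, .data$weight > 0), n),
                   head(filter(tw, .data$weight < 0), n))
  top$feature <- factor(top$feature, levels = rev(top$feature))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$weight, y = .data$feature,
                                    fill = .data$namespace)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "SVM weight", y = NULL,
                  title = "Strongest shallow-linguistic-kernel features") +
    ggplot2::theme_minimal()
}
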