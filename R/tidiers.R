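# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Per-fold metrics of a nested-CV run
#'
#' @param x a `nested_cv` object.
#' @param ... unused.
#' @return tibble with one row per outer fold: `fold_id`, `accuracy`,
#'   `precision`, `recall`, `f1`, `auc` (percent except AUC).
#' @method tidy nested_cv
#' @export
tidy.nested_cv <- function(x, ...) {
  x$metrics |> select("fold_id", "accuracy", "precision", "recall", "f1", "auc")
}

#' One-row summary of a nested-CV run
#'
#' @param x a `nested_cv` object.
#' @param ... unused.
#' @return one-row tibble: model/region, mean and sd of each metric across
#'   folds, mean/sd AUC, and the discordance rate.
#' @method glance nested_cv
#' @export
glance.nested_cv <- function(x, ...) {
  s <- x$aggregate$summary
  wide <- stats::setNames(
    as.list(c(s$mean, s$sd)),
    c(s$metric, paste0(s$metric, "_sd"))
  )
  bind_cols(
    tibble(model = x$model_kind, region = x$region),
    as_tibble(wide),
    tibble(auc = x$aggregate$auc_mean, auc_sd = x$aggregate$auc_sd,
           discordance = x$discordance$mean)
  )
}

#' Mean ROC curve with a +/- 1 sd band
#'
#' @param object a `nested_cv` or `fold_aggregate` object.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fold_aggregate
#' @export
autoplot.fold_aggregate <- function(object, ...) {
  roc <- object$roc
  ggplot2::ggplot(roc, ggplot2::aes(x = .data$fpr, y = .data$tpr_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = pmax(.data$tpr_mean - .data$tpr_sd, 0),
      ymax = pmin(.data$tpr_mean + .data$tpr_sd, 1)), alpha = 0.2) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Mean ROC (AUC %.3f +/- %.3f)",
                      object$auc_mean, object$auc_sd)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fold_aggregate
#' @method autoplot nested_cv
#' @export
autoplot.nested_cv <- function(object, ...) {
  autoplot.fold_aggregate(object$aggregate, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Strict patient-wise accuracy per class across folds
#'
#' Box plots of the per-fold strict patient-wise accuracy, one box per
#' class, mirroring the usual clinical-rule summary figure.
#'
#' @param x a `nested_cv` object.
#' @return a ggplot.
#' @export
plot_patient_accuracy <- function(x) {
  ggplot2::ggplot(x$patient$per_class,
                  ggplot2::aes(x = .data$label, y = .data$accuracy)) +
    ggplot2::geom_boxplot(width = 0.4, outlier.shape = 1) +
    ggplot2::labs(x = NULL, y = "Strict patient-wise accuracy (%)",
                  title = sprintf("%s model, %s region", x$model_kind, x$region)) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Selection-frequency bar chart of the most stable features
#'
#' @param x a `nested_cv` object or a [selection_frequency()] tibble.
#' @param top number of features to show.
#' @return a ggplot.
#' @export
plot_selection_frequency <- function(x, top = 20L) {
  freq <- if (inherits(x, "nested_cv")) x$frequency else x
  freq <- freq |> filter(.data$frequency > 0) |> utils::head(top)
  ggplot2::ggplot(freq, ggplot2::aes(
    x = stats::reorder(.data$feature, .data$frequency),
    y = .data$frequency, fill = .data$source)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Folds selected", fill = "Image source") +
    ggplot2::theme_minimal()
}
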