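#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_abline
#'   geom_vline labs theme_minimal coord_equal
#' @export
ggplot2::autoplot

#' Plot ROC and PR curves of a metrics bundle
#'
#' @param object A `metrics_bundle` with curves, or a `cv_result` (its
#'   pooled aggregate is plotted).
#' @param which `"roc"` or `"pr"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot metrics_bundle
#' @export
autoplot.metrics_bundle <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    if (is.null(object$roc_points)) abort("bundle was computed with curves = FALSE")
    ggplot(object$roc_points, aes(x = .data$fpr, y = .data$tpr)) +
      geom_abline(slope = 1, intercept = 0, linetype = "dashed", colour = "grey60") +
      geom_line() +
      coord_equal() +
      labs(x = "False positive rate", y = "True positive rate",
           title = sprintf("ROC (auROC = %.2f%%)", object$metrics$auROC)) +
      theme_minimal()
  } else {
    if (is.null(object$pr_points)) abort("bundle was computed with curves = FALSE")
    ggplot(object$pr_points, aes(x = .data$recall, y = .data$precision)) +
      geom_line() +
      coord_equal() +
      labs(x = "Recall", y = "Precision",
           title = sprintf("Precision-recall (auPRC = %.2f%%)", object$metrics$auPRC)) +
      theme_minimal()
  }
}

#' @rdname autoplot.metrics_bundle
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, which = c("roc", "pr"), ...) {
  autoplot(object$aggregate, which = which, ...)
}

#' Plot an incremental feature-selection curve
#'
#' auROC and auPRC against the number of top-ranked features; the chosen
#' subset size is marked.
#'
#' @param object A [selection_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot selection_curve
#' @export
autoplot.selection_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curve, c("auROC", "auPRC"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$n_features, y = .data$value,
                   colour = .data$metric)) +
    geom_vline(xintercept = object$chosen_size, linetype = "dashed",
               colour = "grey60") +
    geom_line() +
    geom_point(size = 1) +
    labs(x = "Number of top-ranked features", y = "Cross-validated area (%)",
         colour = NULL,
         title = sprintf("Incremental feature selection (chosen: %d)",
                         object$chosen_size)) +
    theme_minimal()
}
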