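# ggplot2 views of prioritization results and evaluation reports.

#' Plot the prediction-error-versus-features curve
#'
#' Mean inner-validation prediction error as a function of the number of
#' features retained by recursive feature elimination, averaged over all
#' repeats and outer folds; the error-minimizing feature count is marked.
#'
#' @param object An `mcl_prioritization`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mcl_prioritization <- function(object, ...) {
  curve <- object$error_curve
  best <- curve$n_features[which.min(curve$error)]
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_features, y = .data$error)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = best, linetype = "dashed", color = "grey40") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "Features retained",
      y = "Inner-validation prediction error",
      title = "Recursive feature elimination",
      subtitle = paste0("Error minimized at ", best, " features")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a ROC curve for control-target recovery
#'
#' @param scores,positives As in [roc_auc()].
#' @return A ggplot object annotated with the AUC.
#' @export
plot_roc <- function(scores, positives) {
  ev <- roc_auc(scores, positives)
  ggplot2::ggplot(ev$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         color = "grey60") +
    ggplot2::geom_line(color = "firebrick") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = "Control-target recovery",
      subtitle = sprintf("AUC = %.3f", ev$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-feature selection counts
#'
#' How many of the `repeats x outer_folds` feature-selection rounds kept
#' each feature in the error-minimizing model.
#'
#' @param result An `mcl_prioritization`.
#' @param top_n Show only the `top_n` most-selected features.
#' @return A ggplot object.
#' @export
plot_selection_counts <- function(result, top_n = 30L) {
  counts <- arrange(result$selection_counts, dplyr::desc(.data$count))
  counts <- head(counts, top_n)
  counts$feature <- factor(counts$feature, levels = rev(counts$feature))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$count, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = sprintf("Selection count (max %d)",
                  result$config$repeats * result$config$outer_folds),
      y = NULL, title = "Feature selection frequency"
    ) +
    ggplot2::theme_minimal()
}
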