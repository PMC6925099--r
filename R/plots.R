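# ggplot2 views of the main result types

#' @exportS3Method ggplot2::autoplot
autoplot.rt_dlm <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$epoch, y = .data$training_mse)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "training MSE (s²)",
                  title = "Deep RT regressor training loss")
}

#' @exportS3Method ggplot2::autoplot
autoplot.rt_roc <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("RT-error ROC (AUC = %.2f)", object$auc))
}

#' @exportS3Method ggplot2::autoplot
autoplot.rt_projection <- function(object, ...) {
  dat <- data.frame(x = object$fit$model$x, y = object$fit$model$y)
  grid <- data.frame(x = seq(object$anchor_range[1], object$anchor_range[2],
                             length.out = 200))
  grid$y <- predict(object$fit, grid)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::labs(x = "predicted RT, reference method (s)",
                  y = "experimental RT, target method (s)",
                  title = "Predicted-experimental RT projection")
}

#' Predicted versus experimental RT scatter
#'
#' @param predicted Tibble from [predict_rt()] or a numeric vector.
#' @param experimental Experimental RTs in seconds.
#' @return A ggplot.
#' @export
plot_pred_vs_exp <- function(predicted, experimental) {
  if (is.data.frame(predicted)) predicted <- predicted$rt_pred_s
  ggplot2::ggplot(data.frame(x = experimental, y = predicted),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.3) +
    ggplot2::geom_abline(colour = "red") +
    ggplot2::labs(x = "experimental RT (s)", y = "predicted RT (s)")
}

#' Paired error box plots across similarity strata
#'
#' Side-by-side box plots of two error arms (e.g. naive k-NN vs deep
#' model) at each similarity threshold.
#'
#' @param strata_errors Tibble with columns `threshold_pct`, `arm`,
#'   `error_pct`.
#' @return A ggplot.
#' @export
plot_error_strata <- function(strata_errors) {
  ggplot2::ggplot(strata_errors,
                  ggplot2::aes(x = factor(.data$threshold_pct),
                               y = .data$error_pct, fill = .data$arm)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::coord_cartesian(ylim = c(0, stats::quantile(strata_errors$error_pct, 0.95))) +
    ggplot2::labs(x = "similarity threshold (%)", y = "relative RT error (%)")
}
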