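# broom-style tidiers for the fitted objects

#' @exportS3Method generics::tidy
tidy.rt_dlm <- function(x, ...) {
  tibble(epoch = seq_along(x$loss), training_mse = x$loss)
}

#' @exportS3Method generics::glance
glance.rt_dlm <- function(x, ...) {
  tibble(
    n_train = x$n_train,
    n_bits = x$n_bits,
    n_layers = length(x$config$hidden_units),
    n_parameters = sum(purrr::map_dbl(x$weights, length)) +
      sum(purrr::map_dbl(x$biases, length)),
    epochs = x$config$epochs,
    final_training_mse = x$loss[length(x$loss)]
  )
}

#' @exportS3Method generics::tidy
tidy.rt_projection <- function(x, ...) {
  tibble(term = paste0("x^", 0:x$degree),
         estimate = .power_coefficients(x))
}

#' @exportS3Method generics::glance
glance.rt_projection <- function(x, ...) {
  tibble(degree = x$degree, n_anchors = x$n_anchors, robust = x$robust,
         rmse_s = x$residual_summary$rmse_s,
         median_abs_residual_s = x$residual_summary$median_abs_residual_s)
}

#' @exportS3Method generics::tidy
tidy.rt_roc <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.rt_roc <- function(x, ...) {
  tibble(auc = x$auc, n_correct = x$n_pos, n_incorrect = x$n_neg,
         selected_threshold_pct = select_threshold(x))
}

#' @exportS3Method generics::tidy
tidy.rt_error_summary <- function(x, ...) x$errors

#' @exportS3Method generics::glance
glance.rt_error_summary <- function(x, ...) x$summary

#' @exportS3Method generics::tidy
tidy.rt_stat_report <- function(x, ...) {
  if (identical(x$test, "not run")) {
    return(tibble(test = x$test, reason = x$reason))
  }
  if (!is.null(x$p_corrected)) {
    tibble(rep = seq_along(x$p_raw), p_raw = x$p_raw, p_corrected = x$p_corrected)
  } else {
    tibble(test = c("wilcoxon_paired", "ansari_bradley"),
           p_value = c(x$p_location, x$p_scale),
           significance = c(format(x$significance_location),
                            format(x$significance_scale)))
  }
}

#' @exportS3Method generics::glance
glance.rt_stat_report <- function(x, ...) {
  if (identical(x$test, "not run")) {
    return(tibble(test = x$test, reason = x$reason))
  }
  tibble(test = x$test, n = x$n,
         significance = format(x$significance_location))
}

#' @exportS3Method generics::tidy
tidy.rt_ranking <- function(x, ...) x$table

#' @exportS3Method generics::glance
glance.rt_ranking <- function(x, ...) {
  tibble(top3_pct = x$top3_pct,
         n_cases = nrow(x$cases),
         n_cases_gt3 = sum(x$cases$n_candidates > 3))
}
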