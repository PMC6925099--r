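#' Configuration of the deep retention-time regressor
#'
#' Defaults follow the published training setup for fingerprint-based RT
#' regression on a large reverse-phase library: four fully connected relu
#' layers of 1000, 500, 200 and 100 units feeding a single linear output
#' unit, mean-squared-error loss with an L2 weight penalty of 1e-4, Adam
#' with learning rate 0.01, 20 epochs at batch size 35, and a 75/25
#' train/validation split. Training runs the full epoch schedule; there is
#' no early stopping.
#'
#' @param hidden_units Integer vector of hidden-layer widths.
#' @param l2_lambda L2 regularisation weight on all weight matrices.
#' @param learning_rate Adam learning rate.
#' @param epochs Number of full passes over the training set.
#' @param batch_size Mini-batch size.
#' @param train_fraction Fraction of molecules used for training.
#' @param seed Seed controlling weight initialisation and batch shuffling.
#' @return A list of class `dlm_config`.
#' @export
dlm_config <- function(hidden_units = c(1000, 500, 200, 100),
                       l2_lambda = 1e-4,
                       learning_rate = 0.01,
                       epochs = 20,
                       batch_size = 35,
                       train_fraction = 0.75,
                       seed = 1) {
  stopifnot(all(hidden_units > 0), l2_lambda >= 0, learning_rate > 0,
            epochs > 0, batch_size > 0,
            train_fraction > 0, train_fraction < 1)
  structure(list(hidden_units = as.integer(hidden_units),
                 l2_lambda = l2_lambda, learning_rate = learning_rate,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 train_fraction = train_fraction, seed = as.integer(seed)),
            class = "dlm_config")
}

#' Random train/validation split of a molecule table
#'
#' @param molecules Molecule tibble.
#' @param train_fraction Fraction assigned to the training set.
#' @param seed Seed making the split reproducible.
#' @return A list with tibbles `train` and `validation`; the two are
#'   disjoint and together exhaust the input.
#' @export
split_train_val <- function(molecules, train_fraction = 0.75, seed = 1) {
  stopifnot(is.data.frame(molecules), nrow(molecules) >= 2)
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort("`train_fraction` must be in (0, 1)")
  }
  n <- nrow(molecules)
  n_train <- round(n * train_fraction)
  idx <- withr::with_seed(seed, sample.int(n, n_train))
  list(train = molecules[idx, , drop = FALSE],
       validation = molecules[-idx, , drop = FALSE])
}

.check_training_table <- function(train) {
  stopifnot(is.data.frame(train))
  if (nrow(train) == 0) abort("empty training set")
  if (!all(c("fingerprint", "rt_s") %in% names(train))) {
    abort("training set needs `fingerprint` and `rt_s` columns")
  }
  if (anyNA(train$rt_s)) abort("training set has missing retention times")
}

#' Train the deep retention-time regression model
#'
#' Fits a fully connected feed-forward network mapping binary fingerprints
#' to retention time in seconds. Binary inputs are used unscaled and the
#' target is trained in raw seconds. With a fixed `config$seed` the fit is
#' bit-reproducible.
#'
#' @param train Molecule tibble with `fingerprint` and `rt_s`.
#' @param config A [dlm_config()].
#' @return An object of class `rt_dlm` (also `rt_model`) holding the fitted
#'   weights, the per-epoch training loss and the configuration.
#' @seealso [predict_rt()], [evaluate_errors()]
#' @export
train_dlm <- function(train, config = dlm_config()) {
  .check_training_table(train)
  X <- fingerprint_matrix(train)
  y <- as.numeric(train$rt_s)
  dims <- c(ncol(X), config$hidden_units, 1L)
  init <- withr::with_seed(config$seed, {
    W <- lapply(seq_len(length(dims) - 1L), function(l) {
      matrix(rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
             dims[l], dims[l + 1])  # He initialisation for relu
    })
    ord <- vapply(seq_len(config$epochs), function(i) sample.int(nrow(X)),
                  integer(nrow(X)))
    list(W = W, ord = ord)
  })
  b <- lapply(dims[-1], function(k) rep(0, k))
  fit <- .mlp_fit_cpp(X, y, init$W, b, init$ord,
                      config$l2_lambda, config$learning_rate, config$batch_size,
                      0.9, 0.999, 1e-7)
  structure(list(weights = fit$W, biases = fit$b,
                 loss = as.numeric(fit$loss),
                 config = config, n_bits = ncol(X),
                 n_train = nrow(X)),
            class = c("rt_dlm", "rt_model"))
}

#' Predict retention times for a molecule table
#'
#' @param model A fitted model (`rt_dlm` from [train_dlm()] or `rt_rf` from
#'   [train_rf_baseline()]).
#' @param molecules Molecule tibble with a `fingerprint` list-column whose
#'   length matches the training fingerprints.
#' @return A tibble with `mol_id` and `rt_pred_s`.
#' @export
predict_rt <- function(model, molecules) UseMethod("predict_rt")

.check_predict_input <- function(model, molecules) {
  stopifnot(is.data.frame(molecules))
  if (nrow(molecules) == 0) return(NULL)
  X <- fingerprint_matrix(molecules)
  if (ncol(X) != model$n_bits) {
    abort(paste0("fingerprint length ", ncol(X),
                 " does not match the model's ", model$n_bits))
  }
  X
}

#' @export
predict_rt.rt_dlm <- function(model, molecules) {
  X <- .check_predict_input(model, molecules)
  if (is.null(X)) return(tibble(mol_id = character(), rt_pred_s = numeric()))
  tibble(mol_id = molecules$mol_id,
         rt_pred_s = as.numeric(.mlp_predict_cpp(X, model$weights, model$biases)))
}

#' @export
predict.rt_dlm <- function(object, newdata, ...) predict_rt(object, newdata)

#' Random forest comparator for retention-time regression
#'
#' A non-deep baseline on the same fingerprints, exposed through the same
#' prediction and error-evaluation interface as the deep model.
#'
#' @param train Molecule tibble with `fingerprint` and `rt_s`.
#' @param n_trees Number of trees.
#' @param seed Seed for the forest.
#' @return An object of class `rt_rf` (also `rt_model`).
#' @export
train_rf_baseline <- function(train, n_trees = 500, seed = 1) {
  .check_training_table(train)
  X <- fingerprint_matrix(train)
  fit <- ranger::ranger(x = as.data.frame(X), y = as.numeric(train$rt_s),
                        num.trees = n_trees, seed = seed,
                        num.threads = 1)
  structure(list(forest = fit, n_bits = ncol(X), n_train = nrow(X)),
            class = c("rt_rf", "rt_model"))
}

#' @export
predict_rt.rt_rf <- function(model, molecules) {
  X <- .check_predict_input(model, molecules)
  if (is.null(X)) return(tibble(mol_id = character(), rt_pred_s = numeric()))
  p <- predict(model$forest, data = as.data.frame(X), num.threads = 1)
  tibble(mol_id = molecules$mol_id, rt_pred_s = as.numeric(p$predictions))
}

#' Prediction error summary with non-retained-molecule handling
#'
#' Per-molecule relative error is `100 * |pred - exp| / exp` and absolute
#' error is `|pred - exp|` in seconds. Molecules eluting before the void
#' gap (experimental RT below `nonretained_cutoff`) can optionally be
#' excluded, the standard practice when summarising RT prediction error:
#' failing to predict the gap inflates the mean far more than the median.
#'
#' @param predicted,experimental Aligned numeric vectors of RT in seconds,
#'   or tibbles from [predict_rt()] (the `rt_pred_s` column is used).
#' @param exclude_nonretained Drop molecules with experimental RT below the
#'   cutoff before summarising?
#' @param nonretained_cutoff Void-gap cutoff in seconds (default 300,
#'   matching a gradient held at initial conditions for several minutes;
#'   see [detect_nonretained_cutoff()] for a data-driven choice).
#' @param mol_id Optional molecule ids for the per-molecule error table.
#' @return An object of class `rt_error_summary`: summary statistics, the
#'   per-molecule error table, and the count of excluded molecules.
#' @export
evaluate_errors <- function(predicted, experimental,
                            exclude_nonretained = FALSE,
                            nonretained_cutoff = 300,
                            mol_id = NULL) {
  if (is.data.frame(predicted)) {
    mol_id <- mol_id %||% predicted$mol_id
    predicted <- predicted$rt_pred_s
  }
  if (is.data.frame(experimental)) experimental <- experimental$rt_s
  if (length(predicted) != length(experimental)) {
    abort("`predicted` and `experimental` have different lengths")
  }
  if (any(experimental <= 0)) abort("experimental RT must be positive")
  mol_id <- mol_id %||% as.character(seq_along(predicted))
  errors <- tibble(
    mol_id = mol_id,
    rt_pred_s = as.numeric(predicted),
    rt_exp_s = as.numeric(experimental),
    abs_error_s = abs(predicted - experimental),
    rel_error_pct = 100 * abs(predicted - experimental) / experimental
  )
  n_total <- nrow(errors)
  kept <- errors
  n_dropped <- 0L
  if (exclude_nonretained) {
    keep <- errors$rt_exp_s >= nonretained_cutoff
    n_dropped <- sum(!keep)
    kept <- errors[keep, , drop = FALSE]
  }
  if (nrow(kept) == 0) abort("no molecules left to summarise")
  structure(list(
    summary = tibble(
      n = nrow(kept),
      n_dropped_nonretained = n_dropped,
      mean_rel_error_pct = mean(kept$rel_error_pct),
      median_rel_error_pct = median(kept$rel_error_pct),
      mean_abs_error_s = mean(kept$abs_error_s),
      median_abs_error_s = median(kept$abs_error_s)
    ),
    errors = errors,
    excluded_nonretained = exclude_nonretained,
    nonretained_cutoff = if (exclude_nonretained) nonretained_cutoff else NA_real_
  ), class = "rt_error_summary")
}

#' Data-driven void-gap cutoff between non-retained and retained molecules
#'
#' Finds the largest gap in the sorted experimental RTs within the low-RT
#' region and returns its midpoint. Useful when the gradient program (and
#' hence the void gap) is not known.
#'
#' @param rt_s Experimental retention times in seconds.
#' @param search_below Only gaps starting below this RT are considered.
#' @return The cutoff in seconds, or `NA` if no gap can be located.
#' @export
detect_nonretained_cutoff <- function(rt_s, search_below = 600) {
  rt <- sort(rt_s[is.finite(rt_s)])
  if (length(rt) < 2) return(NA_real_)
  lo <- rt[-length(rt)]
  gaps <- diff(rt)
  cand <- which(lo < search_below)
  if (length(cand) == 0) return(NA_real_)
  i <- cand[which.max(gaps[cand])]
  (rt[i] + rt[i + 1]) / 2
}

#' @export
print.rt_error_summary <- function(x, ...) {
  s <- x$summary
  cat("RT prediction error (n = ", s$n, ")\n", sep = "")
  if (x$excluded_nonretained) {
    cat("  non-retained molecules excluded below ", x$nonretained_cutoff,
        " s: ", s$n_dropped_nonretained, " dropped\n", sep = "")
  }
  cat(sprintf("  relative error: mean %.1f%%, median %.1f%%\n",
              s$mean_rel_error_pct, s$median_rel_error_pct))
  cat(sprintf("  absolute error: mean %.1f s, median %.1f s\n",
              s$mean_abs_error_s, s$median_abs_error_s))
  invisible(x)
}
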