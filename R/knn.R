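# Naive similarity baseline and the similarity-stratified statistical
# comparison machinery. The baseline encodes the heuristic "similar
# molecules elute at similar times": a query molecule's RT is estimated by
# the median RT of its k Tanimoto-nearest training molecules.

#' Naive k-NN median retention-time prediction
#'
#' For each query molecule, finds the `k` training molecules with the
#' highest Tanimoto similarity and predicts the median of their retention
#' times. Similarity ties at the k-th neighbour are broken by training
#' `mol_id` order so results are reproducible.
#'
#' @param query,training Molecule tibbles with `fingerprint` columns;
#'   `training` must also have `rt_s`.
#' @param k Number of neighbours (default 3).
#' @return A tibble with `mol_id` and `rt_pred_s`.
#' @export
knn_median_rt <- function(query, training, k = 3) {
  stopifnot(k >= 1, is.data.frame(training), nrow(training) >= 1)
  if (k > nrow(training)) abort("`k` exceeds the training set size")
  if (anyNA(training$rt_s)) abort("training set has missing retention times")
  S <- tanimoto_matrix(query, training)
  tie_rank <- order(training$mol_id)         # stable tie-break on mol_id
  pos <- integer(nrow(training)); pos[tie_rank] <- seq_along(tie_rank)
  rt <- as.numeric(training$rt_s)
  pred <- vapply(seq_len(nrow(S)), function(i) {
    o <- order(-S[i, ], pos)[seq_len(k)]
    median(rt[o])
  }, numeric(1))
  tibble(mol_id = query$mol_id, rt_pred_s = pred)
}

#' Stratify validation molecules by best similarity to the training set
#'
#' A validation molecule belongs to the stratum at threshold `t` when at
#' least one training molecule is `>= t` percent Tanimoto-similar to it, so
#' strata are nested from the highest threshold downwards.
#'
#' @param validation,training Molecule tibbles with `fingerprint` columns.
#' @param thresholds Similarity thresholds in percent (default the grid
#'   95, 90, 80, 70, 50 used for similarity-stratified error comparison).
#' @return An object of class `rt_strata`: per-molecule best similarity
#'   (`$molecules`) and per-threshold membership (`$strata`).
#' @export
stratify_by_similarity <- function(validation, training,
                                   thresholds = c(95, 90, 80, 70, 50)) {
  stopifnot(all(thresholds > 0), all(thresholds <= 100))
  S <- tanimoto_matrix(validation, training)
  best <- apply(S, 1, max)
  molecules <- tibble(mol_id = validation$mol_id, max_similarity_pct = unname(best))
  strata <- tibble(
    threshold_pct = sort(thresholds, decreasing = TRUE),
    mol_ids = purrr::map(sort(thresholds, decreasing = TRUE),
                         ~ molecules$mol_id[best >= .x]),
  )
  strata$n <- lengths(strata$mol_ids)
  structure(list(molecules = molecules, strata = strata), class = "rt_strata")
}

#' @export
print.rt_strata <- function(x, ...) {
  cat("Similarity strata (validation vs training):\n")
  print(dplyr::select(x$strata, "threshold_pct", "n"))
  invisible(x)
}

.significance_level <- function(p, levels = c(1e-4, 1e-3, 1e-2, 0.05)) {
  for (lev in sort(levels)) if (!is.na(p) && p < lev) return(lev)
  "ns"
}

#' Paired location and scale comparison of two error samples
#'
#' Compares two aligned per-molecule error vectors (e.g. naive k-NN versus
#' deep-model relative errors on the same molecules): a paired Wilcoxon
#' signed-rank test for location and an Ansari-Bradley test for scale,
#' with medians and interquartile ranges of both arms.
#'
#' @param errors_a,errors_b Aligned numeric vectors (same molecules).
#' @param labels Names of the two arms, used in the report.
#' @return An object of class `rt_stat_report`.
#' @export
compare_paired_errors <- function(errors_a, errors_b,
                                  labels = c("a", "b")) {
  if (length(errors_a) != length(errors_b)) abort("arms have different lengths")
  if (length(errors_a) < 2) abort("need at least 2 pairs")
  d <- errors_a - errors_b
  all_tied <- all(d == 0)
  wil <- if (all_tied) NA_real_ else
    suppressWarnings(wilcox.test(errors_a, errors_b, paired = TRUE)$p.value)
  ans <- suppressWarnings(tryCatch(
    ansari.test(errors_a, errors_b)$p.value, error = function(e) NA_real_))
  iqr <- function(x) unname(diff(quantile(x, c(0.25, 0.75))))
  structure(list(
    test = "paired Wilcoxon signed-rank (location) + Ansari-Bradley (scale)",
    n = length(errors_a),
    all_tied = all_tied,
    p_location = wil,
    p_scale = ans,
    significance_location = if (all_tied) "ns" else .significance_level(wil),
    significance_scale = .significance_level(ans),
    arms = tibble(arm = labels,
                  median = c(median(errors_a), median(errors_b)),
                  iqr = c(iqr(errors_a), iqr(errors_b)))
  ), class = "rt_stat_report")
}

#' Repeated subsampled Wilcoxon rank-sum test with Bonferroni correction
#'
#' Compares two groups of different sizes by repeatedly (default 1000
#' times) subsampling the larger group down to the smaller group's size,
#' running a two-sample Wilcoxon rank-sum test on each subsample, and
#' Bonferroni-correcting the resulting P values by the number of
#' repetitions. The reported significance level is the smallest of
#' 0.05, 0.01, 0.001, 0.0001 under which at least 95 percent of the
#' corrected P values fall; otherwise `ns`. When the groups already have
#' equal sizes every repetition runs the same full test.
#'
#' @param group_a,group_b Numeric error vectors (different molecules).
#' @param reps Number of subsample repetitions.
#' @param seed Optional seed for the subsampling.
#' @return An object of class `rt_stat_report` carrying all raw and
#'   corrected P values.
#' @export
subsample_bonferroni_test <- function(group_a, group_b, reps = 1000, seed = NULL) {
  stopifnot(reps >= 1)
  if (length(group_a) == 0 || length(group_b) == 0) abort("both groups must be nonempty")
  run <- function() {
    n_min <- min(length(group_a), length(group_b))
    vapply(seq_len(reps), function(i) {
      a <- if (length(group_a) > n_min) sample(group_a, n_min) else group_a
      b <- if (length(group_b) > n_min) sample(group_b, n_min) else group_b
      suppressWarnings(wilcox.test(a, b)$p.value)
    }, numeric(1))
  }
  p_raw <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  p_corr <- pmin(p_raw * reps, 1)
  level <- "ns"
  for (lev in c(0.05, 0.01, 0.001, 1e-4)) {
    if (mean(p_corr < lev) >= 0.95) level <- lev
  }
  iqr <- function(x) unname(diff(quantile(x, c(0.25, 0.75))))
  structure(list(
    test = "subsampled two-sample Wilcoxon rank-sum, Bonferroni-corrected",
    n = min(length(group_a), length(group_b)),
    reps = reps,
    p_raw = p_raw,
    p_corrected = p_corr,
    significance_location = level,
    arms = tibble(arm = c("a", "b"),
                  n = c(length(group_a), length(group_b)),
                  median = c(median(group_a), median(group_b)),
                  iqr = c(iqr(group_a), iqr(group_b)))
  ), class = "rt_stat_report")
}

#' Does having a similar training molecule reduce prediction error?
#'
#' Splits validation molecules into those with at least one training
#' neighbour at or above the similarity threshold and those without, then
#' compares the two groups' prediction errors with
#' [subsample_bonferroni_test()].
#'
#' @param validation,training Molecule tibbles with `fingerprint` columns.
#' @param errors Per-molecule prediction errors aligned with `validation`
#'   (e.g. relative errors from [evaluate_errors()]).
#' @param threshold Similarity threshold in percent (default 90).
#' @param reps,seed Passed to [subsample_bonferroni_test()].
#' @return An `rt_stat_report`, or a list with `test = "not run"` and the
#'   group sizes when either group is empty.
#' @export
similarity_impact_analysis <- function(validation, training, errors,
                                       threshold = 90, reps = 1000, seed = NULL) {
  if (length(errors) != nrow(validation)) {
    abort("`errors` must align with `validation` rows")
  }
  S <- tanimoto_matrix(validation, training)
  has_nbr <- apply(S, 1, max) >= threshold
  n_with <- sum(has_nbr); n_without <- sum(!has_nbr)
  if (n_with == 0 || n_without == 0) {
    return(structure(list(test = "not run", reason = "one group is empty",
                          n_with_neighbor = n_with,
                          n_without_neighbor = n_without),
                     class = "rt_stat_report"))
  }
  rep_out <- subsample_bonferroni_test(errors[has_nbr], errors[!has_nbr],
                                       reps = reps, seed = seed)
  rep_out$arms$arm <- c("with_neighbor", "without_neighbor")
  rep_out$threshold_pct <- threshold
  rep_out
}

#' @export
print.rt_stat_report <- function(x, ...) {
  cat(x$test, "\n")
  if (identical(x$test, "not run")) {
    cat("  reason:", x$reason, "\n")
    return(invisible(x))
  }
  if (!is.null(x$p_location)) {
    cat(sprintf("  location P = %.3g (%s), scale P = %.3g (%s), n = %d\n",
                x$p_location, format(x$significance_location),
                x$p_scale, format(x$significance_scale), x$n))
  } else {
    cat(sprintf("  %d reps, significance level: %s\n", x$reps,
                format(x$significance_location)))
  }
  print(x$arms)
  invisible(x)
}
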