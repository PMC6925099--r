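# Accurate-mass candidate annotation: retrieve all library molecules whose
# adduct m/z matches an observed ion within a ppm window, rank them by
# projected-RT error, pick an error threshold from a ROC sweep, and report
# filtering and ranking performance.

#' Accurate-mass candidate search
#'
#' For every query ion, returns the library molecules whose theoretical
#' adduct m/z matches the observed m/z within `tol_ppm` (default 10 ppm,
#' the usual accurate-mass database window). Relative RT error per
#' candidate is `100 * |candidate projected RT - query experimental RT| /
#' query experimental RT`.
#'
#' @param query_ions Tibble with `query_id`, `mz`, `adduct` (`"M+H"` or
#'   `"M-H"`), `rt_exp_s`, and optionally `true_mol_id` for evaluation.
#' @param library Tibble with `mol_id`, `mono_mass` and `rt_proj_s`
#'   (candidate RT projected onto the query's method).
#' @param tol_ppm Mass tolerance in ppm.
#' @return A candidate tibble: one row per (query, candidate) pair with
#'   `query_id`, `mol_id`, `theo_mz`, `ppm_error`, `rt_proj_s`, `rt_exp_s`,
#'   `rel_rt_error_pct` and, when truth is known, `is_truth`. Queries with
#'   no match simply contribute no rows.
#' @export
candidate_search <- function(query_ions, library, tol_ppm = 10) {
  stopifnot(is.data.frame(query_ions), is.data.frame(library))
  if (nrow(library) == 0) abort("empty candidate library")
  if (!all(c("mol_id", "mono_mass", "rt_proj_s") %in% names(library))) {
    abort("library needs `mol_id`, `mono_mass`, `rt_proj_s`")
  }
  if (!all(c("query_id", "mz", "adduct", "rt_exp_s") %in% names(query_ions))) {
    abort("query_ions needs `query_id`, `mz`, `adduct`, `rt_exp_s`")
  }
  has_truth <- "true_mol_id" %in% names(query_ions)
  purrr::map_dfr(seq_len(nrow(query_ions)), function(i) {
    q <- query_ions[i, ]
    theo <- adduct_mz(library$mono_mass, q$adduct)
    hit <- ppm_match(q$mz, theo, tol_ppm)
    if (!any(hit)) return(NULL)
    out <- tibble(
      query_id = q$query_id,
      mol_id = library$mol_id[hit],
      theo_mz = theo[hit],
      ppm_error = 1e6 * abs(q$mz - theo[hit]) / theo[hit],
      rt_proj_s = library$rt_proj_s[hit],
      rt_exp_s = q$rt_exp_s,
      rel_rt_error_pct = 100 * abs(library$rt_proj_s[hit] - q$rt_exp_s) / q$rt_exp_s
    )
    if (has_truth) out$is_truth <- out$mol_id == q$true_mol_id
    out
  })
}

#' Rank candidates by ascending RT error
#'
#' Within each query, candidates are ordered by relative RT error with
#' ties broken by ascending `mol_id` (deterministic).
#'
#' @param candidates Candidate tibble from [candidate_search()].
#' @return The same tibble with a `rank` column, ordered within query.
#' @export
rank_candidates <- function(candidates) {
  stopifnot(is.data.frame(candidates))
  candidates |>
    dplyr::group_by(.data$query_id) |>
    dplyr::arrange(.data$rel_rt_error_pct, .data$mol_id, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' ROC sweep over the relative RT error threshold
#'
#' At each threshold `t` of the grid, a candidate whose RT error is at or
#' under `t` is called positive: `TP` counts correct identities called
#' positive, `FN` correct identities above the threshold, `FP` incorrect
#' candidates called positive and `TN` incorrect candidates above it.
#' `TPR = TP / (TP + FN)`, `FPR = FP / (FP + TN)`; the AUC is the
#' trapezoidal area under the (FPR, TPR) curve.
#'
#' @param candidates Candidate tibble with an `is_truth` column.
#' @param grid Error thresholds in percent (default 0 to 100 by 2.5).
#' @return An object of class `rt_roc` with the per-threshold confusion
#'   table, TPR/FPR and the AUC.
#' @export
roc_curve <- function(candidates, grid = seq(0, 100, by = 2.5)) {
  stopifnot(is.data.frame(candidates), "is_truth" %in% names(candidates))
  err <- candidates$rel_rt_error_pct
  truth <- candidates$is_truth
  n_pos <- sum(truth)
  if (n_pos == 0) abort("no correct identities among the candidates; TPR undefined")
  n_neg <- sum(!truth)
  tab <- tibble(
    threshold_pct = grid,
    tp = vapply(grid, function(t) sum(truth & err <= t), numeric(1)),
    fp = vapply(grid, function(t) sum(!truth & err <= t), numeric(1))
  )
  tab$fn <- n_pos - tab$tp
  tab$tn <- n_neg - tab$fp
  tab$tpr <- tab$tp / n_pos
  tab$fpr <- if (n_neg > 0) tab$fp / n_neg else NA_real_
  x <- c(0, tab$fpr); y <- c(0, tab$tpr)
  auc <- if (n_neg > 0) sum(diff(x) * (head(y, -1) + y[-1]) / 2) else NA_real_
  structure(list(table = tab, auc = auc, n_pos = n_pos, n_neg = n_neg),
            class = "rt_roc")
}

#' Select the filtering threshold maximising TPR - FPR
#'
#' Youden's J statistic over the ROC grid; ties resolve to the smallest
#' threshold.
#'
#' @param roc An `rt_roc` from [roc_curve()].
#' @return The selected threshold in percent.
#' @export
select_threshold <- function(roc) {
  stopifnot(inherits(roc, "rt_roc"))
  j <- roc$table$tpr - roc$table$fpr
  roc$table$threshold_pct[which.max(j)]  # which.max takes the first = smallest
}

#' Filter candidates by an RT error threshold
#'
#' Keeps candidates with relative RT error at or under the threshold and
#' reports per-query and aggregate counts, including the fraction of
#' correct identities that the filter itself discards.
#'
#' @param candidates Candidate tibble (with `is_truth` when truth is known).
#' @param threshold Relative RT error threshold in percent.
#' @return An object of class `rt_filter`: `$retained` (the filtered
#'   tibble), `$counts` (per-query before/after), and when truth is known
#'   `$n_truth`, `$n_truth_lost` and `$lost_truth_fraction`.
#' @export
filter_candidates <- function(candidates, threshold) {
  stopifnot(is.data.frame(candidates), threshold >= 0)
  keep <- candidates$rel_rt_error_pct <= threshold
  counts <- candidates |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(n_before = dplyr::n(),
                     n_after = sum(.data$rel_rt_error_pct <= threshold),
                     .groups = "drop")
  out <- list(retained = candidates[keep, , drop = FALSE],
              counts = counts,
              threshold_pct = threshold,
              n_before = nrow(candidates),
              n_after = sum(keep))
  if ("is_truth" %in% names(candidates)) {
    n_truth <- sum(candidates$is_truth)
    n_lost <- sum(candidates$is_truth & !keep)
    out$n_truth <- n_truth
    out$n_truth_lost <- n_lost
    out$lost_truth_fraction <- if (n_truth > 0) n_lost / n_truth else NA_real_
  }
  structure(out, class = "rt_filter")
}

#' Candidate ranking report
#'
#' For ranks r in 1..3 and candidate-count conditions m in 1..3, the
#' percentage of annotation cases with more than m candidates in which the
#' correct identity sits exactly at rank r, plus the top-3 summary: the
#' percentage of cases with more than 3 candidates whose correct identity
#' ranks in the top three. Cases whose truth is not among the candidates
#' count in the denominators but can never hit a rank.
#'
#' @param candidates Candidate tibble with `is_truth` (ranked internally
#'   with [rank_candidates()] if no `rank` column is present).
#' @return An object of class `rt_ranking` with the rank-by-condition
#'   percentage table (`$table`, `NA` where a denominator is empty),
#'   `$top3_pct` and `$cases` (per-query candidate count and truth rank).
#' @export
ranking_report <- function(candidates) {
  stopifnot(is.data.frame(candidates), "is_truth" %in% names(candidates))
  if (!"rank" %in% names(candidates)) candidates <- rank_candidates(candidates)
  cases <- candidates |>
    dplyr::group_by(.data$query_id) |>
    dplyr::summarise(
      n_candidates = dplyr::n(),
      truth_rank = if (any(.data$is_truth)) min(.data$rank[.data$is_truth]) else Inf,
      .groups = "drop")
  grid <- tidyr::expand_grid(rank = 1:3, min_candidates = 1:3)
  tab <- grid |>
    dplyr::mutate(
      n_cases = purrr::map_int(.data$min_candidates,
                               ~ sum(cases$n_candidates > .x)),
      pct = purrr::map2_dbl(.data$rank, .data$min_candidates, function(r, m) {
        den <- cases$n_candidates > m
        if (!any(den)) return(NA_real_)
        100 * sum(cases$truth_rank[den] == r) / sum(den)
      }))
  den3 <- cases$n_candidates > 3
  top3 <- if (any(den3)) 100 * sum(cases$truth_rank[den3] <= 3) / sum(den3) else NA_real_
  structure(list(table = tab, top3_pct = top3, cases = cases),
            class = "rt_ranking")
}

#' @export
print.rt_roc <- function(x, ...) {
  cat(sprintf("ROC over RT error thresholds: AUC = %.3f (%d correct, %d incorrect)\n",
              x$auc, x$n_pos, x$n_neg))
  invisible(x)
}

#' @export
print.rt_filter <- function(x, ...) {
  cat(sprintf("RT error filter at %.1f%%: %d -> %d candidates\n",
              x$threshold_pct, x$n_before, x$n_after))
  if (!is.null(x$n_truth)) {
    cat(sprintf("  correct identities filtered out: %d of %d (%.0f%%)\n",
                x$n_truth_lost, x$n_truth, 100 * x$lost_truth_fraction))
  }
  invisible(x)
}

#' @export
print.rt_ranking <- function(x, ...) {
  cat("Candidate ranking (% of cases, by rank and candidate-count condition):\n")
  print(tidyr::pivot_wider(x$table, id_cols = "rank",
                           names_from = "min_candidates",
                           names_prefix = "more_than_",
                           values_from = "pct"))
  cat(sprintf("top-3 (cases with > 3 candidates): %.1f%%\n", x$top3_pct))
  invisible(x)
}
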