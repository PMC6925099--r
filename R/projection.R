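# Projection of predicted retention times onto another chromatographic
# method. Reverse-phase methods broadly conserve elution order, so a
# smooth monotone-ish map fitted on a few dozen molecules identified in
# both methods suffices to transfer an RT scale.

#' Fit a polynomial projection from predicted to target-method RT
#'
#' Least-squares regression of the target method's experimental RT on an
#' orthogonal-polynomial basis of the reference-scale predicted RT
#' (degree 4 by default). An optional iteratively reweighted mode
#' (Tukey bisquare) damps the influence of aberrant predictions among the
#' anchors; it is off by default.
#'
#' @param anchors Tibble with columns `rt_pred_s` (predicted RT on the
#'   reference scale) and `rt_exp_s` (experimental RT on the target
#'   method), optionally `mol_id`.
#' @param degree Polynomial degree (default 4).
#' @param robust Use iteratively reweighted least squares?
#' @param seed Optional seed recorded with the fit, so a fit from a random
#'   anchor draw can be reproduced.
#' @return An object of class `rt_projection`.
#' @export
fit_projection <- function(anchors, degree = 4, robust = FALSE, seed = NULL) {
  stopifnot(is.data.frame(anchors),
            all(c("rt_pred_s", "rt_exp_s") %in% names(anchors)))
  x <- as.numeric(anchors$rt_pred_s); y <- as.numeric(anchors$rt_exp_s)
  if (!all(is.finite(x)) || !all(is.finite(y))) abort("anchors must be finite")
  if (length(x) < degree + 1) {
    abort(paste0("need at least degree + 1 = ", degree + 1, " anchors, got ", length(x)))
  }
  if (length(unique(x)) < degree + 1) {
    abort("too few distinct predicted-RT values for the requested degree")
  }
  dat <- data.frame(x = x, y = y)
  fit <- lm(y ~ poly(x, degree), data = dat)
  w <- rep(1, length(x))
  if (robust) {
    for (it in 1:20) {
      r <- y - predict(fit, dat)
      s <- median(abs(r)) / 0.6745
      if (s == 0) break
      u <- r / (4.685 * s)
      w_new <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      if (max(abs(w_new - w)) < 1e-8) break
      w <- w_new
      fit <- lm(y ~ poly(x, degree), data = dat, weights = w)
    }
  }
  res <- y - predict(fit, dat)
  structure(list(
    fit = fit, degree = degree, robust = robust,
    anchor_ids = if ("mol_id" %in% names(anchors)) anchors$mol_id else NULL,
    anchor_range = range(x),
    n_anchors = length(x),
    seed = seed,
    residuals = res,
    residual_summary = tibble(rmse_s = sqrt(mean(res^2)),
                              median_abs_residual_s = median(abs(res)))
  ), class = "rt_projection")
}

#' Project predicted RTs onto the target method's scale
#'
#' Values outside the anchor range are still evaluated but flagged as
#' extrapolations, not clamped.
#'
#' @param fn An `rt_projection` from [fit_projection()].
#' @param rt_pred_s Predicted RTs on the reference scale.
#' @return A tibble with `rt_pred_s`, `rt_proj_s` and `extrapolated`.
#' @export
project_rt <- function(fn, rt_pred_s) {
  stopifnot(inherits(fn, "rt_projection"))
  x <- as.numeric(rt_pred_s)
  tibble(
    rt_pred_s = x,
    rt_proj_s = as.numeric(predict(fn$fit, data.frame(x = x))),
    extrapolated = x < fn$anchor_range[1] | x > fn$anchor_range[2]
  )
}

#' Error summary of projected versus experimental RT on the target method
#'
#' Same error definitions as [evaluate_errors()], computed on the target
#' method's time scale (no non-retained handling).
#'
#' @param projected Projected RTs (vector, or tibble from [project_rt()]).
#' @param experimental Experimental RTs on the target method, seconds.
#' @param mol_id Optional ids for the per-molecule table.
#' @return An `rt_error_summary`.
#' @export
projection_error_summary <- function(projected, experimental, mol_id = NULL) {
  if (is.data.frame(projected)) projected <- projected$rt_proj_s
  evaluate_errors(projected, experimental, exclude_nonretained = FALSE,
                  mol_id = mol_id)
}

# power-basis coefficients equivalent to the orthogonal-basis fit,
# recovered by interpolating the fitted curve
.power_coefficients <- function(fn) {
  x <- seq(fn$anchor_range[1], fn$anchor_range[2], length.out = fn$degree + 1)
  if (length(unique(x)) < fn$degree + 1) x <- seq_along(x)  # degenerate range
  y <- predict(fn$fit, data.frame(x = x))
  unname(solve(outer(x, 0:fn$degree, `^`), y))
}

#' Serialise a fitted projection to JSON
#'
#' Writes degree, power-basis coefficients, anchor ids, anchor range and
#' the recorded seed, enough to re-evaluate or audit the projection
#' without the fitted object.
#'
#' @param fn An `rt_projection`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_projection_json <- function(fn, path) {
  stopifnot(inherits(fn, "rt_projection"))
  jsonlite::write_json(list(
    degree = fn$degree,
    coefficients_power_basis = .power_coefficients(fn),
    anchor_ids = fn$anchor_ids,
    anchor_range_s = fn$anchor_range,
    n_anchors = fn$n_anchors,
    seed = fn$seed,
    residual_rmse_s = fn$residual_summary$rmse_s
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.rt_projection <- function(x, ...) {
  cat(sprintf("Polynomial RT projection (degree %d%s), %d anchors\n",
              x$degree, if (x$robust) ", robust" else "", x$n_anchors))
  cat(sprintf("  anchor range: %.0f-%.0f s; residual RMSE %.2f s\n",
              x$anchor_range[1], x$anchor_range[2],
              x$residual_summary$rmse_s))
  invisible(x)
}
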