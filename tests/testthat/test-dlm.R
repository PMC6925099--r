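# unit tests of the deep regressor plumbing; model-recovery behaviour at
# realistic scale lives in test-acceptance.R

tiny_dlm_config <- function(seed = 3, epochs = 8) {
  dlm_config(hidden_units = c(32, 16), epochs = epochs, batch_size = 10,
             seed = seed)
}

test_that("train/validation split is disjoint, exhaustive and seed-stable", {
  lib <- gen_library(tiny_config(100))
  sp <- split_train_val(lib, 0.75, seed = 11)
  expect_equal(nrow(sp$train), 75)
  expect_equal(nrow(sp$validation), 25)
  expect_length(intersect(sp$train$mol_id, sp$validation$mol_id), 0)
  expect_setequal(c(sp$train$mol_id, sp$validation$mol_id), lib$mol_id)
  sp2 <- split_train_val(lib, 0.75, seed = 11)
  expect_identical(sp$train$mol_id, sp2$train$mol_id)
  sp3 <- split_train_val(lib, 0.75, seed = 12)
  expect_false(identical(sp$train$mol_id, sp3$train$mol_id))
  expect_error(split_train_val(lib, 1.2), "train_fraction")
})

test_that("training reduces the loss and runs the full epoch schedule", {
  lib <- gen_library(tiny_config(60, seed = 2))
  fit <- train_dlm(lib, tiny_dlm_config())
  expect_length(fit$loss, 8)
  expect_lt(fit$loss[8], fit$loss[1])
  expect_s3_class(fit, "rt_dlm")
  expect_equal(glance(fit)$n_train, 60)
})

test_that("a constant target is learned to near-constant predictions", {
  lib <- gen_library(tiny_config(60, seed = 5))
  const <- lib; const$rt_s <- 500
  fit <- train_dlm(const, tiny_dlm_config(epochs = 20))
  pred <- predict_rt(fit, const)$rt_pred_s
  expect_equal(mean(pred), 500, tolerance = 0.05)
  # prediction MSE around the constant is far below the variance of a
  # nonconstant control target
  expect_lt(mean((pred - 500)^2), 0.05 * var(lib$rt_s))
})

test_that("fixed-seed training is bit-reproducible", {
  lib <- gen_library(tiny_config(50, seed = 8))
  f1 <- train_dlm(lib, tiny_dlm_config(seed = 42))
  f2 <- train_dlm(lib, tiny_dlm_config(seed = 42))
  expect_identical(f1$weights, f2$weights)
  expect_identical(f1$loss, f2$loss)
  f3 <- train_dlm(lib, tiny_dlm_config(seed = 43))
  expect_false(identical(f1$weights, f3$weights))
})

test_that("prediction handles empty input, duplicates and length mismatch", {
  lib <- gen_library(tiny_config(40, seed = 3))
  fit <- train_dlm(lib, tiny_dlm_config())
  empty <- lib[0, ]
  expect_equal(nrow(predict_rt(fit, empty)), 0)
  dup <- lib[c(1, 1), ]
  p <- predict_rt(fit, dup)
  expect_equal(p$rt_pred_s[1], p$rt_pred_s[2])
  expect_true(all(is.finite(predict_rt(fit, lib)$rt_pred_s)))
  other <- gen_library(generator_config(n_molecules = 5, n_bits = 64, seed = 1))
  expect_error(predict_rt(fit, other), "does not match")
})

test_that("evaluate_errors reproduces a hand-computed toy table", {
  pred <- c(110, 100, 95, 600, 240)
  exp_ <- c(100, 100, 100, 30, 200)
  es <- evaluate_errors(pred, exp_)
  # hand-computed: rel = 10, 0, 5, 1900, 20 %; abs = 10, 0, 5, 570, 40 s
  expect_equal(es$errors$rel_error_pct, c(10, 0, 5, 1900, 20))
  expect_equal(es$errors$abs_error_s, c(10, 0, 5, 570, 40))
  expect_equal(es$summary$mean_rel_error_pct, mean(c(10, 0, 5, 1900, 20)))
  expect_equal(es$summary$median_abs_error_s, 10)

  # excluding the non-retained molecule (exp 30 s < 60 s cutoff)
  es2 <- evaluate_errors(pred, exp_, exclude_nonretained = TRUE,
                         nonretained_cutoff = 60)
  expect_equal(es2$summary$n, 4)
  expect_equal(es2$summary$n_dropped_nonretained, 1)
  expect_lt(es2$summary$mean_rel_error_pct, es$summary$mean_rel_error_pct)
  expect_equal(es2$summary$mean_rel_error_pct, mean(c(10, 0, 5, 20)))
  # the unfiltered per-molecule table still has all 5 rows
  expect_equal(nrow(es2$errors), 5)
})

test_that("identical predictions give an all-zero error summary", {
  es <- evaluate_errors(c(100, 250, 900), c(100, 250, 900))
  expect_equal(es$summary$mean_rel_error_pct, 0)
  expect_equal(es$summary$median_abs_error_s, 0)
  expect_error(evaluate_errors(c(1, 2), c(1, 2, 3)), "length")
  expect_error(evaluate_errors(c(1, 2), c(0, 2)), "positive")
})

test_that("excluding non-retained molecules never increases the evaluated count", {
  lib <- gen_library(tiny_config(200, seed = 9))
  pred <- lib$rt_true_s
  for (cutoff in c(0, 100, 300, 500)) {
    all_in <- evaluate_errors(pred, lib$rt_s)
    excl <- evaluate_errors(pred, lib$rt_s, exclude_nonretained = TRUE,
                            nonretained_cutoff = cutoff)
    expect_lte(excl$summary$n, all_in$summary$n)
  }
})

test_that("the void-gap detector finds the constructed gap", {
  lib <- gen_library(tiny_config(300, seed = 13))
  cut <- detect_nonretained_cutoff(lib$rt_s)
  expect_gt(cut, max(lib$rt_s[lib$nonretained]))
  expect_lt(cut, min(lib$rt_s[!lib$nonretained]))
})

test_that("random forest comparator shares the prediction interface", {
  lib <- gen_library(tiny_config(80, seed = 4))
  sp <- split_train_val(lib, 0.75, seed = 1)
  rf <- train_rf_baseline(sp$train, n_trees = 50, seed = 7)
  p <- predict_rt(rf, sp$validation)
  expect_true(all(is.finite(p$rt_pred_s)))
  es <- evaluate_errors(p, sp$validation, exclude_nonretained = TRUE)
  expect_true(is.finite(es$summary$median_abs_error_s))
  rf2 <- train_rf_baseline(sp$train, n_trees = 50, seed = 7)
  expect_equal(predict_rt(rf2, sp$validation), p)
})
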