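test_that("accurate-mass search applies the ppm window per adduct", {
  library_tbl <- tibble::tibble(
    mol_id = c("a", "b", "c"),
    mono_mass = c(100.0000, 100.0005, 200.0),
    rt_proj_s = c(100, 200, 300))
  # ion at the M+H m/z of mass 100.0005: a is 5 ppm off, b exact, c far
  q <- tibble::tibble(query_id = "q1", mz = 101.007776, adduct = "M+H",
                      rt_exp_s = 150)
  hits <- candidate_search(q, library_tbl, tol_ppm = 10)
  expect_setequal(hits$mol_id, c("a", "b"))
  expect_equal(hits$ppm_error[hits$mol_id == "b"], 0, tolerance = 1e-6)

  exact <- candidate_search(q, library_tbl, tol_ppm = 0)
  expect_equal(exact$mol_id, "b")

  far <- tibble::tibble(query_id = "q2", mz = 500, adduct = "M-H", rt_exp_s = 10)
  expect_equal(nrow(candidate_search(far, library_tbl)), 0)
  expect_error(candidate_search(q, library_tbl[0, ]), "empty")
})

test_that("candidates rank by RT error with deterministic tie-break", {
  cands <- make_candidates("q1", err = c(12, 3, 30), truth = c(FALSE, TRUE, FALSE),
                           mol_id = c("x", "vanillic", "z"))
  r <- rank_candidates(cands)
  expect_equal(r$mol_id[r$rank == 1], "vanillic")  # smallest error ranks first
  single <- rank_candidates(make_candidates("q2", 40, TRUE))
  expect_equal(single$rank, 1)
  tied <- rank_candidates(make_candidates("q3", c(5, 5), c(FALSE, TRUE),
                                          mol_id = c("m2", "m1")))
  expect_equal(tied$mol_id, c("m1", "m2"))  # mol_id breaks the tie
})

test_that("ROC confusion counts equal hand enumeration on a six-candidate toy", {
  # correct errors {5, 20, 40}; incorrect errors {10, 30, 80}
  toy <- make_candidates(c("q1", "q2", "q3", "q1", "q2", "q3"),
                         err = c(5, 20, 40, 10, 30, 80),
                         truth = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  roc <- roc_curve(toy)
  tab <- roc$table
  pick <- function(t) tab[tab$threshold_pct == t, ]
  # by hand at 0:   nothing <= 0
  expect_equal(unlist(pick(0)[, c("tp", "fp", "fn", "tn")]),
               c(tp = 0, fp = 0, fn = 3, tn = 3))
  # at 7.5: correct {5}; incorrect none
  expect_equal(unlist(pick(7.5)[, c("tp", "fp", "fn", "tn")]),
               c(tp = 1, fp = 0, fn = 2, tn = 3))
  # at 25: correct {5,20}; incorrect {10}
  expect_equal(unlist(pick(25)[, c("tp", "fp", "fn", "tn")]),
               c(tp = 2, fp = 1, fn = 1, tn = 2))
  # at 40 (on the grid): correct {5,20,40} — boundary counts as under
  expect_equal(unlist(pick(40)[, c("tp", "fp", "fn", "tn")]),
               c(tp = 3, fp = 2, fn = 0, tn = 1))
  # at 100: everything
  expect_equal(unlist(pick(100)[, c("tp", "fp", "fn", "tn")]),
               c(tp = 3, fp = 3, fn = 0, tn = 0))
  # TP + FN is threshold-invariant; counts always sum to all candidates
  expect_true(all(tab$tp + tab$fn == 3))
  expect_true(all(tab$tp + tab$fn + tab$fp + tab$tn == 6))
  # TPR and FPR never decrease along the threshold grid
  expect_true(all(diff(tab$tpr) >= 0))
  expect_true(all(diff(tab$fpr) >= 0))
})

test_that("trapezoid AUC equals the tie-corrected rank statistic", {
  # separable toy: all correct errors below all incorrect errors
  sep <- make_candidates(rep("q", 6), err = c(2.5, 5, 7.5, 50, 60, 70),
                         truth = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  roc <- roc_curve(sep)
  expect_equal(roc$auc, 1)
  expect_true(any(roc$table$tpr == 1 & roc$table$fpr == 0))

  # same-distribution errors: AUC near 1/2
  set.seed(12)
  n <- 4000
  same <- make_candidates(rep("q", n),
                          err = sample(seq(0, 100, 2.5), n, replace = TRUE),
                          truth = rep(c(TRUE, FALSE), n / 2))
  expect_equal(roc_curve(same)$auc, 0.5, tolerance = 0.03)

  expect_error(roc_curve(make_candidates("q", 10, FALSE)), "no correct")
})

test_that("threshold selection maximises Youden's J with smallest-threshold ties", {
  sep <- make_candidates(rep("q", 4), err = c(5, 10, 60, 80),
                         truth = c(TRUE, TRUE, FALSE, FALSE))
  roc <- roc_curve(sep)
  thr <- select_threshold(roc)
  j <- roc$table$tpr - roc$table$fpr
  expect_equal(thr, roc$table$threshold_pct[which.max(j)])
  expect_equal(max(j), 1)
  expect_gte(thr, 10); expect_lt(thr, 60)

  # identical error distributions -> J = 0 everywhere -> smallest grid point
  flat <- make_candidates(rep("q", 4), err = c(10, 10, 50, 50),
                          truth = c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(select_threshold(roc_curve(flat)), 0)

  # brute-force argmax agreement on a random toy
  set.seed(3)
  rnd <- make_candidates(rep("q", 40), err = runif(40, 0, 100),
                         truth = rep(c(TRUE, FALSE), 20))
  rr <- roc_curve(rnd)
  grid_j <- vapply(rr$table$threshold_pct, function(t) {
    tp <- sum(rnd$is_truth & rnd$rel_rt_error_pct <= t)
    fp <- sum(!rnd$is_truth & rnd$rel_rt_error_pct <= t)
    tp / 20 - fp / 20
  }, numeric(1))
  expect_equal(select_threshold(rr), rr$table$threshold_pct[which.max(grid_j)])
})

test_that("filtering bookkeeping is exact", {
  toy <- make_candidates(c("q1", "q1", "q1", "q2", "q2"),
                         err = c(0, 30, 55, 10, 90),
                         truth = c(FALSE, TRUE, FALSE, TRUE, FALSE))
  all_kept <- filter_candidates(toy, 100)
  expect_equal(all_kept$n_after, 5)
  expect_equal(all_kept$lost_truth_fraction, 0)
  zero <- filter_candidates(toy, 0)
  expect_equal(zero$retained$rel_rt_error_pct, 0)
  # truth at error 30 is lost under a 27.5% threshold; truth at 10 survives
  f <- filter_candidates(toy, 27.5)
  expect_equal(f$n_truth_lost, 1)
  expect_equal(f$lost_truth_fraction, 0.5)
  expect_equal(f$counts$n_after[f$counts$query_id == "q1"], 1)
})

test_that("ranking report equals hand counts on five constructed cases", {
  # case: n_candidates, truth rank:
  #   q1: 1 cand, rank 1; q2: 2, rank 2; q3: 4, rank 1; q4: 4, rank 4; q5: 5, rank 3
  cands <- dplyr::bind_rows(
    make_candidates("q1", 5, TRUE),
    make_candidates("q2", c(5, 10), c(FALSE, TRUE)),
    make_candidates("q3", c(1, 2, 3, 4), c(TRUE, FALSE, FALSE, FALSE)),
    make_candidates("q4", c(1, 2, 3, 4), c(FALSE, FALSE, FALSE, TRUE)),
    make_candidates("q5", c(1, 2, 3, 4, 5), c(FALSE, FALSE, TRUE, FALSE, FALSE)))
  rep_ <- ranking_report(cands)
  tab <- rep_$table
  g <- function(r, m) tab$pct[tab$rank == r & tab$min_candidates == m]
  # >1 candidate: q2..q5 (4 cases); rank1 hits: q3 -> 25%; rank2: q2 -> 25%
  expect_equal(g(1, 1), 25); expect_equal(g(2, 1), 25); expect_equal(g(3, 1), 25)
  # >3 candidates: q3, q4, q5; rank1: q3 -> 33.3%; rank3: q5; top3: q3+q5 of 3
  expect_equal(g(1, 3), 100 / 3); expect_equal(g(3, 3), 100 / 3)
  expect_equal(rep_$top3_pct, 200 / 3)
  expect_equal(glance(rep_)$n_cases_gt3, 3)

  # all single-candidate cases: every denominator empty
  singles <- dplyr::bind_rows(make_candidates("a", 1, TRUE),
                              make_candidates("b", 2, TRUE))
  rs <- ranking_report(singles)
  expect_true(all(is.na(rs$table$pct)))
  expect_true(is.na(rs$top3_pct))
})

test_that("widening the ppm tolerance never removes candidates", {
  lib <- gen_library(tiny_config(150, seed = 61))
  ecm <- gen_ecm(lib, ecm_config(seed = 3))
  lib_search <- tibble::tibble(mol_id = ecm$table$mol_id,
                               mono_mass = lib$mono_mass[match(ecm$table$mol_id, lib$mol_id)],
                               rt_proj_s = ecm$table$rt_ecm_s)
  q <- gen_query_ions(lib, ecm, n_queries = 40, seed = 4)
  n_prev <- -1
  for (tol in c(1, 5, 10, 50)) {
    n <- nrow(candidate_search(q, lib_search, tol_ppm = tol))
    expect_gte(n, n_prev)
    n_prev <- n
  }
})
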