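test_that("generators are fully deterministic under fixed seeds", {
  cfg <- tiny_config(80, seed = 123)
  l1 <- gen_library(cfg); l2 <- gen_library(cfg)
  expect_identical(l1, l2)
  e1 <- gen_ecm(l1, ecm_config(seed = 7)); e2 <- gen_ecm(l1, ecm_config(seed = 7))
  expect_identical(e1$table, e2$table)
  q1 <- gen_query_ions(l1, e1, seed = 9); q2 <- gen_query_ions(l1, e1, seed = 9)
  expect_identical(q1, q2)
  l3 <- gen_library(tiny_config(80, seed = 124))
  expect_false(identical(l1$rt_s, l3$rt_s))
})

test_that("zero noise makes duplicated fingerprints share their RT exactly", {
  cfg <- tiny_config(150, seed = 33, rt_noise_sd_s = 0, family_rt_sd_s = 0,
                     duplicate_flip_range = c(0, 0), duplicate_rate = 0.5)
  lib <- gen_library(cfg)
  key <- vapply(lib$fingerprint, paste, character(1), collapse = "")
  dup_groups <- split(lib$rt_s, key)
  dup_groups <- dup_groups[lengths(dup_groups) > 1]
  expect_gt(length(dup_groups), 0)
  for (g in dup_groups) expect_equal(max(g) - min(g), 0)
})

test_that("the non-retained fraction sits below the gap, nothing inside it", {
  cfg <- generator_config(n_molecules = 1000, n_bits = 256,
                          nonretained_fraction = 0.1, seed = 3)
  lib <- gen_library(cfg)
  # floor(1000 * 0.1), up to latent-score ties at the boundary
  expect_equal(sum(lib$nonretained), 100, tolerance = 0.05)
  expect_true(all(lib$rt_s[lib$nonretained] <= cfg$nonretained_range_s[2]))
  expect_true(all(lib$rt_s[!lib$nonretained] >= cfg$rt_floor_s))
  in_gap <- lib$rt_s > cfg$nonretained_range_s[2] & lib$rt_s < cfg$rt_floor_s
  expect_equal(sum(in_gap), 0)
})

test_that("cluster mates with zero flip rate are Tanimoto-identical", {
  cfg <- tiny_config(20, seed = 2, cluster_flip_rate = 0, duplicate_rate = 0)
  cfg$n_clusters <- 2
  lib <- gen_library(cfg)
  same <- which(lib$cluster == lib$cluster[1])
  expect_gt(length(same), 1)
  expect_equal(tanimoto(lib$fingerprint[[same[1]]], lib$fingerprint[[same[2]]]), 100)
})

test_that("default library populates every similarity stratum", {
  lib <- gen_library(generator_config())
  sp <- split_train_val(lib, 0.75, seed = 1)
  st <- stratify_by_similarity(sp$validation, sp$train)
  expect_true(all(st$strata$n > 0))
})

test_that("identity warp with zero noise reproduces the reference scale", {
  lib <- gen_library(tiny_config(100, seed = 5))
  ecm <- gen_ecm(lib, ecm_config(warp = "identity", noise_sd_s = 0, seed = 1))
  expect_equal(ecm$table$rt_ecm_s, ecm$table$rt_ref_s)
  expect_false(any(lib$nonretained[match(ecm$table$mol_id, lib$mol_id)]))
})

test_that("monotone warps preserve elution order exactly at zero noise", {
  lib <- gen_library(tiny_config(100, seed = 6))
  ecm <- gen_ecm(lib, ecm_config(warp = "beta", shape1 = 3, shape2 = 1.5,
                                 noise_sd_s = 0, seed = 1))
  rho <- suppressWarnings(cor(ecm$table$rt_ref_s, ecm$table$rt_ecm_s,
                              method = "spearman"))
  expect_equal(rho, 1)
})

test_that("non-monotone warp parameters are rejected", {
  lib <- gen_library(tiny_config(50, seed = 7))
  bad <- ecm_config(warp = "poly", poly_coefficients = c(0, 1, -2))
  expect_error(gen_ecm(lib, bad), "strictly increasing")
})

test_that("zero mass noise keeps the true identity among candidates", {
  lib <- gen_library(tiny_config(200, seed = 8))
  ecm <- gen_ecm(lib, ecm_config(seed = 2))
  q <- gen_query_ions(lib, ecm, n_queries = 50, mass_noise_ppm = 0, seed = 3)
  search_lib <- tibble::tibble(
    mol_id = ecm$table$mol_id,
    mono_mass = lib$mono_mass[match(ecm$table$mol_id, lib$mol_id)],
    rt_proj_s = ecm$table$rt_ecm_s)
  cands <- candidate_search(q, search_lib, tol_ppm = 10)
  found <- cands |>
    dplyr::group_by(query_id) |>
    dplyr::summarise(hit = any(is_truth), .groups = "drop")
  expect_equal(nrow(found), 50)
  expect_true(all(found$hit))
})

test_that("mass near-collisions create multi-candidate query sets", {
  lib <- gen_library(generator_config(n_molecules = 600, n_bits = 256, seed = 9))
  ecm <- gen_ecm(lib, ecm_config(seed = 2))
  q <- gen_query_ions(lib, ecm, seed = 3)
  search_lib <- tibble::tibble(
    mol_id = ecm$table$mol_id,
    mono_mass = lib$mono_mass[match(ecm$table$mol_id, lib$mol_id)],
    rt_proj_s = ecm$table$rt_ecm_s)
  cands <- candidate_search(q, search_lib)
  sizes <- table(cands$query_id)
  expect_gt(sum(sizes > 1), 20)
  expect_gt(sum(sizes > 3), 0)
  # empty selection gives an empty query table
  empty <- gen_query_ions(lib, ecm, n_queries = 0, seed = 1)
  expect_equal(nrow(empty), 0)
})

test_that("library CSV round-trips through read_molecules with truth sidecar", {
  lib <- gen_library(tiny_config(25, seed = 10))
  path <- withr::local_tempfile(fileext = ".csv")
  write_library_csv(lib, path)
  back <- read_molecules(path, format = "fp_csv")
  expect_equal(nrow(back), 25)
  expect_identical(back$fingerprint[[7]], lib$fingerprint[[7]])
  expect_equal(back$rt_s, lib$rt_s)
  truth <- jsonlite::read_json(paste0(path, ".truth.json"), simplifyVector = TRUE)
  expect_equal(length(truth$weights), 128)
})
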