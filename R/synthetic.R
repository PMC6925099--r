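# Seeded generators for a synthetic fingerprint/RT library and external
# chromatographic methods, so the full pipeline (regression, k-NN
# comparison, projection, annotation) can run and be validated without any
# external download. The latent model is exactly what the documentation
# states: RT is a sparse-linear function of the fingerprint bits, optionally
# squashed through a monotone probit, plus a family-shared idiosyncratic
# offset and replicate noise. There is no hidden structure beyond this.

#' Configuration of the synthetic molecule library generator
#'
#' The generated library mimics the statistical structure RT-prediction
#' analyses rely on: cluster/similarity structure in binary fingerprints
#' (cluster prototypes plus near-duplicate "homologue" variants, which
#' populate the high-similarity strata), retention time from a sparse
#' linear map of the bits with a mild monotone nonlinearity, replicate
#' noise of 18 s (a typical median replicate variability for a long
#' reverse-phase gradient), a family-shared idiosyncratic RT component that
#' fingerprints cannot explain (so molecules with a near-twin in the
#' training set are genuinely easier to predict), a non-retained fraction
#' eluting before the void gap, and monoisotopic masses with occasional
#' near-collisions to exercise multi-candidate accurate-mass search.
#'
#' @param n_molecules Library size.
#' @param n_bits Fingerprint length.
#' @param n_clusters Number of cluster prototypes.
#' @param bit_density Prototype bit density.
#' @param cluster_flip_rate Per-bit flip rate of a cluster member relative
#'   to its prototype.
#' @param duplicate_rate Probability that a molecule is a near-duplicate of
#'   an earlier one (same family) instead of a fresh cluster member.
#' @param duplicate_flip_range Range of the per-event near-duplicate bit
#'   flip rate (drawn uniformly, giving a spread of 80-99 percent Tanimoto
#'   similarities).
#' @param latent_n_weights Number of nonzero weights of the sparse latent map.
#' @param latent_map `"probit"` (default; mild monotone nonlinearity) or
#'   `"linear"` (RT affine in the fingerprint bits, for exact
#'   noise-floor analyses).
#' @param rt_range_s Retained-molecule RT range in seconds.
#' @param rt_noise_sd_s Replicate noise sd in seconds (default 18).
#' @param family_rt_sd_s Sd of the family-shared idiosyncratic RT offset in
#'   seconds (default 90; set 0 to disable).
#' @param nonretained_fraction Fraction of molecules eluting before the
#'   void gap.
#' @param nonretained_range_s RT range of non-retained molecules.
#' @param rt_floor_s Lowest observable retained RT (gradient start);
#'   retained RTs are clipped here, leaving an empty gap above the
#'   non-retained range.
#' @param mass_range_da Monoisotopic mass range in Da.
#' @param mass_collision_rate Fraction of molecules whose mass is placed
#'   within a few ppm of an earlier molecule's.
#' @param mass_collision_ppm Half-width (ppm) of the collision placement.
#' @param seed Seed; a fixed seed reproduces the library exactly.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_molecules = 2000,
                             n_bits = 1024,
                             n_clusters = 60,
                             bit_density = 0.1,
                             cluster_flip_rate = 0.012,
                             duplicate_rate = 0.18,
                             duplicate_flip_range = c(0.001, 0.008),
                             latent_n_weights = 100,
                             latent_map = c("probit", "linear"),
                             rt_range_s = c(360, 1260),
                             rt_noise_sd_s = 18,
                             family_rt_sd_s = 90,
                             nonretained_fraction = 0.08,
                             nonretained_range_s = c(20, 100),
                             rt_floor_s = 310,
                             mass_range_da = c(80, 600),
                             mass_collision_rate = 0.2,
                             mass_collision_ppm = 5,
                             seed = 1) {
  latent_map <- match.arg(latent_map)
  stopifnot(n_molecules >= 1, n_bits >= 8, n_clusters >= 1,
            bit_density > 0, bit_density < 1,
            cluster_flip_rate >= 0, cluster_flip_rate <= 1,
            duplicate_rate >= 0, duplicate_rate <= 1,
            rt_noise_sd_s >= 0, family_rt_sd_s >= 0,
            nonretained_fraction >= 0, nonretained_fraction < 1,
            rt_range_s[1] < rt_range_s[2],
            nonretained_range_s[2] <= rt_floor_s)
  structure(as.list(environment()), class = "generator_config")
}

#' Generate a synthetic molecule library
#'
#' See [generator_config()] for the generating model. Non-retained
#' molecules are the `nonretained_fraction` with the weakest latent
#' retention scores; their RTs are spread evenly over the non-retained
#' range, leaving the void gap up to `rt_floor_s` empty.
#'
#' @param config A [generator_config()].
#' @return A molecule tibble (`mol_id`, `smiles`, `fingerprint`,
#'   `mono_mass`, `rt_s`) with extra columns `rt_true_s` (noise-free RT),
#'   `family`, `cluster` and `nonretained`. The latent truth (weights,
#'   config) is attached as the `"latent"` attribute.
#' @export
gen_library <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  c_ <- config
  withr::with_seed(c_$seed, {
    n <- c_$n_molecules; d <- c_$n_bits
    proto <- matrix(rbinom(c_$n_clusters * d, 1, c_$bit_density),
                    c_$n_clusters, d)
    X <- matrix(0L, n, d)
    fam <- integer(n); clu <- integer(n); n_fam <- 0L
    for (i in seq_len(n)) {
      if (i > 1 && runif(1) < c_$duplicate_rate) {
        j <- sample.int(i - 1L, 1)
        fr <- runif(1, c_$duplicate_flip_range[1], c_$duplicate_flip_range[2])
        X[i, ] <- abs(X[j, ] - rbinom(d, 1, fr))
        fam[i] <- fam[j]; clu[i] <- clu[j]
      } else {
        clu[i] <- sample.int(c_$n_clusters, 1)
        X[i, ] <- abs(proto[clu[i], ] - rbinom(d, 1, c_$cluster_flip_rate))
        n_fam <- n_fam + 1L; fam[i] <- n_fam
      }
    }
    w <- rep(0, d)
    nz <- sample.int(d, min(c_$latent_n_weights, d))
    w[nz] <- rnorm(length(nz))
    s <- drop(X %*% w)
    # latent score -> retained RT over the configured range
    z <- if (sd(s) > 0) (s - mean(s)) / sd(s) else rep(0, length(s))
    u <- if (c_$latent_map == "probit") pnorm(z) else {
      if (diff(range(s)) > 0) (s - min(s)) / diff(range(s)) else rep(0.5, length(s))
    }
    rt_true <- c_$rt_range_s[1] + diff(c_$rt_range_s) * u
    # family-shared idiosyncratic offset (structure the fingerprint misses)
    if (c_$family_rt_sd_s > 0) {
      rt_true <- rt_true + rnorm(n_fam, 0, c_$family_rt_sd_s)[fam]
    }
    # weakest-retention fraction elutes before the void gap
    n_nr <- floor(n * c_$nonretained_fraction)
    nonret <- rep(FALSE, n)
    if (n_nr > 0) {
      # score-threshold rule, tie-inclusive, so identical fingerprints can
      # never straddle the retained/non-retained boundary
      nonret <- s <= sort(s)[n_nr]
      r <- rank(s[nonret], ties.method = "average")
      rt_true[nonret] <- c_$nonretained_range_s[1] +
        diff(c_$nonretained_range_s) * (r - 0.5) / sum(nonret)
    }
    rt_obs <- rt_true + rnorm(n, 0, c_$rt_noise_sd_s)
    rt_obs[!nonret] <- pmax(rt_obs[!nonret], c_$rt_floor_s)
    rt_obs[nonret] <- pmin(pmax(rt_obs[nonret], 1), c_$nonretained_range_s[2])
    # monoisotopic masses with seeded near-collisions
    mass <- runif(n, c_$mass_range_da[1], c_$mass_range_da[2])
    for (i in seq_len(n)) {
      if (i > 1 && runif(1) < c_$mass_collision_rate) {
        j <- sample.int(i - 1L, 1)
        mass[i] <- mass[j] *
          (1 + runif(1, -c_$mass_collision_ppm, c_$mass_collision_ppm) * 1e-6)
      }
    }
    lib <- tibble(
      mol_id = sprintf("M%05d", seq_len(n)),
      smiles = NA_character_,
      fingerprint = lapply(seq_len(n), function(i) X[i, ]),
      mono_mass = mass,
      rt_s = rt_obs,
      rt_true_s = rt_true,
      family = fam,
      cluster = clu,
      nonretained = nonret
    )
    attr(lib, "latent") <- list(weights = w, config = c_)
    lib
  })
}

#' Configuration of a synthetic external chromatographic method
#'
#' An external method is a noisy strictly monotone warp of the reference RT
#' scale, emulating reverse-phase methods that conserve elution order but
#' differ in gradient and run length. Short methods (< 300 s) and long
#' methods (>= 1500 s) are obtained through `method_length_s`.
#'
#' @param warp `"beta"` (scaled cumulative-beta warp, default), `"identity"`,
#'   or `"poly"` with `poly_coefficients` in the power basis over the
#'   normalised reference scale.
#' @param shape1,shape2 Beta-CDF warp shapes.
#' @param poly_coefficients Power-basis coefficients for `warp = "poly"`,
#'   applied to the reference RT normalised to `[0, 1]`; must be monotone
#'   increasing there.
#' @param method_length_s Target method run length in seconds.
#' @param t0_s Dead (void) time of the target method: the earliest RT the
#'   beta warp can produce. Default 5 percent of `method_length_s`.
#' @param noise_sd_s Measurement noise sd on the target scale; default
#'   2 percent of `method_length_s`.
#' @param n_anchors Number of identified anchor molecules to draw.
#' @param seed Seed for noise and anchor selection.
#' @return A list of class `ecm_config`.
#' @export
ecm_config <- function(warp = c("beta", "identity", "poly"),
                       shape1 = 2, shape2 = 2,
                       poly_coefficients = NULL,
                       method_length_s = 1500,
                       t0_s = NULL,
                       noise_sd_s = NULL,
                       n_anchors = 50,
                       seed = 1) {
  warp <- match.arg(warp)
  noise_sd_s <- noise_sd_s %||% (0.02 * method_length_s)
  t0_s <- t0_s %||% (0.05 * method_length_s)
  stopifnot(method_length_s > 0, noise_sd_s >= 0, n_anchors >= 1,
            t0_s >= 0, t0_s < method_length_s)
  if (warp == "poly" && is.null(poly_coefficients)) {
    abort("`poly_coefficients` required for warp = \"poly\"")
  }
  structure(list(warp = warp, shape1 = shape1, shape2 = shape2,
                 poly_coefficients = poly_coefficients,
                 method_length_s = method_length_s, t0_s = t0_s,
                 noise_sd_s = noise_sd_s,
                 n_anchors = as.integer(n_anchors), seed = as.integer(seed)),
            class = "ecm_config")
}

.ecm_warp_fn <- function(config, ref_range) {
  r0 <- ref_range[1]; r1 <- ref_range[2]
  norm <- function(t) (t - r0) / (r1 - r0)
  fn <- switch(config$warp,
    identity = function(t) t,
    beta = function(t) config$t0_s +
      (config$method_length_s - config$t0_s) *
      stats::pbeta(pmin(pmax(norm(t), 0), 1), config$shape1, config$shape2),
    poly = function(t) {
      u <- norm(t)
      drop(outer(u, seq_along(config$poly_coefficients) - 1, `^`) %*%
             config$poly_coefficients)
    })
  grid <- seq(r0, r1, length.out = 512)
  if (any(diff(fn(grid)) <= 0)) {
    abort("warp is not strictly increasing over the reference RT range")
  }
  fn
}

#' Generate a synthetic external chromatographic method
#'
#' Applies the configured monotone warp to the noise-free reference RT of
#' every retained library molecule, adds measurement noise, and draws a
#' seeded subset of "identified" anchor molecules. The true warp function
#' is returned for recovery analyses.
#'
#' @param library A library from [gen_library()].
#' @param config An [ecm_config()].
#' @return An object of class `rt_ecm`: `$table` (per-molecule `mol_id`,
#'   `rt_ref_s`, `rt_ecm_s`, `is_anchor`), `$anchors` (the anchor rows),
#'   `$warp` (the true warp function) and `$config`.
#' @export
gen_ecm <- function(library, config = ecm_config()) {
  stopifnot(inherits(config, "ecm_config"), is.data.frame(library))
  retained <- library[!library$nonretained, , drop = FALSE]
  ref <- retained$rt_true_s
  fn <- .ecm_warp_fn(config, range(ref))
  withr::with_seed(config$seed, {
    rt_ecm <- fn(ref) + rnorm(length(ref), 0, config$noise_sd_s)
    anchor_idx <- sample.int(nrow(retained), min(config$n_anchors, nrow(retained)))
  })
  tab <- tibble(
    mol_id = retained$mol_id,
    rt_ref_s = ref,
    rt_ecm_s = rt_ecm,
    is_anchor = seq_len(nrow(retained)) %in% anchor_idx
  )
  structure(list(table = tab,
                 anchors = tab[tab$is_anchor, , drop = FALSE],
                 warp = fn, config = config),
            class = "rt_ecm")
}

#' Generate annotation query ions with known truth
#'
#' One protonated or deprotonated ion per selected molecule, with m/z set
#' to the adduct m/z of the molecule's monoisotopic mass plus sub-ppm mass
#' noise, and the experimental RT taken from the external method table.
#' The generating molecule is recorded as the true identity.
#'
#' @param library A library from [gen_library()].
#' @param ecm An `rt_ecm` from [gen_ecm()] (supplies `rt_exp_s`).
#' @param n_queries Number of query ions (default: all molecules in the
#'   ECM table).
#' @param adducts Adduct labels sampled uniformly per query.
#' @param mass_noise_ppm Half-width of the uniform m/z noise in ppm.
#' @param seed Seed.
#' @return A query-ion tibble (`query_id`, `mz`, `adduct`, `rt_exp_s`,
#'   `true_mol_id`) ready for [candidate_search()].
#' @export
gen_query_ions <- function(library, ecm, n_queries = NULL,
                           adducts = c("M+H", "M-H"),
                           mass_noise_ppm = 0.2, seed = 1) {
  stopifnot(inherits(ecm, "rt_ecm"))
  adducts <- .normalize_adduct(adducts)
  tab <- dplyr::inner_join(ecm$table,
                           library[, c("mol_id", "mono_mass")], by = "mol_id")
  withr::with_seed(seed, {
    if (!is.null(n_queries)) {
      n_queries <- min(n_queries, nrow(tab))
      tab <- tab[sample.int(nrow(tab), n_queries), , drop = FALSE]
    }
    add <- sample(adducts, nrow(tab), replace = TRUE)
    jitter <- runif(nrow(tab), -mass_noise_ppm, mass_noise_ppm) * 1e-6
    tibble(
      query_id = paste0("Q_", tab$mol_id),
      mz = adduct_mz(tab$mono_mass, add) * (1 + jitter),
      adduct = add,
      rt_exp_s = tab$rt_ecm_s,
      true_mol_id = tab$mol_id
    )
  })
}

#' Write a synthetic library in the fingerprint-CSV dialect
#'
#' Produces the same `fp_csv` layout [read_molecules()] accepts
#' (`mol_id`, `rt_s`, `mono_mass`, one 0/1 column per bit), plus a truth
#' JSON sidecar with the latent weights and the generator configuration.
#'
#' @param library A library from [gen_library()].
#' @param path Output CSV path; the truth JSON goes to `<path>.truth.json`.
#' @return `path`, invisibly.
#' @export
write_library_csv <- function(library, path) {
  bits <- do.call(rbind, library$fingerprint)
  colnames(bits) <- sprintf("fp_%04d", seq_len(ncol(bits)))
  df <- cbind(data.frame(mol_id = library$mol_id,
                         rt_s = library$rt_s,
                         mono_mass = library$mono_mass),
              as.data.frame(bits))
  utils::write.csv(df, path, row.names = FALSE)
  latent <- attr(library, "latent")
  if (!is.null(latent)) {
    cfg <- latent$config
    class(cfg) <- NULL
    jsonlite::write_json(list(weights = latent$weights, config = cfg),
                         paste0(path, ".truth.json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
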