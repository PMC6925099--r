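# shared fixtures and independent oracles, all built in code

# tiny fast generator config for unit tests
tiny_config <- function(n = 100, seed = 1, ...) {
  generator_config(n_molecules = n, n_bits = 128, n_clusters = 8,
                   latent_n_weights = 30, seed = seed, ...)
}

# brute-force k-NN median-RT oracle with the same mol_id tie rule
knn_oracle <- function(query, training, k) {
  pos <- integer(nrow(training))
  pos[order(training$mol_id)] <- seq_len(nrow(training))
  vapply(seq_len(nrow(query)), function(i) {
    sims <- vapply(seq_len(nrow(training)), function(j) {
      tanimoto(query$fingerprint[[i]], training$fingerprint[[j]])
    }, numeric(1))
    o <- order(-sims, pos)[seq_len(k)]
    median(training$rt_s[o])
  }, numeric(1))
}

# tie-corrected rank-statistic AUC oracle: P(correct error < incorrect
# error) with ties counted half
auc_oracle <- function(err_correct, err_incorrect) {
  s <- 0
  for (a in err_correct) for (b in err_incorrect) {
    s <- s + (a < b) + 0.5 * (a == b)
  }
  s / (length(err_correct) * length(err_incorrect))
}

# candidate tibble builder for annotation tests
make_candidates <- function(query_id, err, truth, mol_id = NULL) {
  tibble::tibble(
    query_id = query_id,
    mol_id = mol_id %||% sprintf("c%03d", seq_along(err)),
    rel_rt_error_pct = err,
    is_truth = truth
  )
}

iqr <- function(x) unname(diff(quantile(x, c(0.25, 0.75))))
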