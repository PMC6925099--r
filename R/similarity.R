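#' Tanimoto similarity between two binary fingerprints
#'
#' `100 * |a AND b| / |a OR b|`: 0 means no shared substructure bits,
#' 100 means identical fingerprints.
#'
#' @param a,b Binary (0/1) vectors of equal length.
#' @return Similarity as a percentage in `[0, 100]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) abort("fingerprints have different lengths")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) abort("Tanimoto similarity is undefined for two all-zero fingerprints")
  100 * sum(a & b) / u
}

#' Pairwise Tanimoto similarity matrix
#'
#' Computes all query-versus-reference Tanimoto similarities with one
#' matrix product, which is what makes similarity stratification and the
#' k-NN baseline fast on thousands of molecules.
#'
#' @param query,reference Molecule tibbles with `fingerprint` list-columns,
#'   or 0/1 matrices (rows = molecules).
#' @return A numeric matrix of similarities in percent, queries in rows,
#'   with `mol_id` dimnames when available.
#' @export
tanimoto_matrix <- function(query, reference) {
  Q <- if (is.matrix(query)) query else fingerprint_matrix(query)
  R <- if (is.matrix(reference)) reference else fingerprint_matrix(reference)
  if (ncol(Q) != ncol(R)) abort("fingerprint lengths differ between query and reference")
  inter <- Q %*% t(R)
  uni <- outer(rowSums(Q), rowSums(R), "+") - inter
  if (any(uni == 0)) abort("Tanimoto similarity is undefined for two all-zero fingerprints")
  100 * inter / uni
}
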