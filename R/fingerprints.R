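# Circular (Morgan-type) binary fingerprints computed from SDF connection
# tables. The open equivalent of ECFP: atom environments of increasing
# radius are hashed to integer identifiers and folded onto a fixed-length
# bit vector. Radius 2 with 1024 bits corresponds to the ECFP4-class
# fingerprints standard in QSRR work.

# default valences used to infer implicit hydrogen counts
.VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3,
              S = 2, Cl = 1, Br = 1, I = 1)

.ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11,
                    Si = 14, P = 15, S = 16, Cl = 17, K = 19, Br = 35, I = 53)

# monoisotopic masses of the most abundant isotope
.MONO_MASS <- c(H = 1.00782503, B = 11.00930536, C = 12.0, N = 14.00307401,
                O = 15.99491462, F = 18.99840322, Na = 22.98976928,
                Si = 27.97692653, P = 30.97376199, S = 31.97207100,
                Cl = 34.96885268, K = 38.96370649, Br = 78.91833760,
                I = 126.90447300)

# deterministic 31-bit polynomial rolling hash; inputs are small
# non-negative integers so double arithmetic stays exact
.hash_ints <- function(x) {
  h <- 17
  for (v in x) h <- (h * 31 + v) %% 2147483647
  h
}

# parse one ChemmineR SDF object into element symbols and a bond table
.sdf_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- gsub("_.*$", "", rownames(ab))
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0) {
    matrix(numeric(0), 0, 3)
  } else {
    cbind(as.numeric(bb[, 1]), as.numeric(bb[, 2]), as.numeric(bb[, 3]))
  }
  list(elem = elem, bonds = bonds)
}

# Morgan fingerprint over an atom/bond graph
.fp_from_graph <- function(elem, bonds, n_bits, radius) {
  n <- length(elem)
  if (n == 0) abort("structure has no atoms")
  nbr <- vector("list", n)
  ord <- vector("list", n)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      i <- bonds[r, 1]; j <- bonds[r, 2]; o <- bonds[r, 3]
      nbr[[i]] <- c(nbr[[i]], j); ord[[i]] <- c(ord[[i]], o)
      nbr[[j]] <- c(nbr[[j]], i); ord[[j]] <- c(ord[[j]], o)
    }
  }
  deg <- lengths(nbr)
  bsum <- vapply(ord, function(o) sum(o %||% 0), numeric(1))
  val <- .VALENCE[elem]
  hcnt <- pmax(0, ifelse(is.na(val), 0, val - bsum))
  anum <- .ATOMIC_NUMBER[elem]
  anum[is.na(anum)] <- 0
  ids <- vapply(seq_len(n), function(i) {
    .hash_ints(c(anum[i], deg[i], bsum[i], hcnt[i]))
  }, numeric(1))
  all_ids <- ids
  if (radius > 0) {
    for (r in seq_len(radius)) {
      new_ids <- vapply(seq_len(n), function(i) {
        if (deg[i] == 0) return(.hash_ints(c(r, ids[i])))
        env <- ord[[i]] * 2147483647 + ids[nbr[[i]]]
        o <- order(env)
        .hash_ints(c(r, ids[i], as.vector(rbind(ord[[i]][o], ids[nbr[[i]]][o]))))
      }, numeric(1))
      ids <- new_ids
      all_ids <- c(all_ids, ids)
    }
  }
  fp <- integer(n_bits)
  fp[(all_ids %% n_bits) + 1] <- 1L
  fp
}

.smiles_to_sdfset <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort("ChemmineR is required to parse structures")
  }
  suppressWarnings(ChemmineR::smiles2sdf(smiles))
}

#' Compute a circular (Morgan-type) binary fingerprint
#'
#' Hashes atom environments of increasing radius into a fixed-length binary
#' vector, the open equivalent of extended connectivity fingerprints (ECFP).
#' Identical structures with identical parameters always give identical
#' bit vectors.
#'
#' @param structure A character vector of SMILES strings, or a
#'   `ChemmineR::SDFset`.
#' @param n_bits Fingerprint length in bits (default 1024).
#' @param radius Maximum atom-environment radius in bonds (default 2,
#'   the ECFP4 equivalent).
#' @return For a single structure, an integer vector of 0/1 of length
#'   `n_bits`; for several structures, a list of such vectors.
#' @examples
#' \dontrun{
#' fp <- compute_fingerprint("CCO")
#' sum(fp)
#' }
#' @export
compute_fingerprint <- function(structure, n_bits = 1024, radius = 2) {
  stopifnot(n_bits >= 1, radius >= 0)
  scalar <- is.character(structure) && length(structure) == 1
  if (is.character(structure)) {
    structure <- .smiles_to_sdfset(structure)
  }
  if (!inherits(structure, "SDFset")) {
    abort("`structure` must be SMILES strings or an SDFset")
  }
  fps <- lapply(seq_along(structure), function(i) {
    g <- .sdf_graph(structure[[i]])
    .fp_from_graph(g$elem, g$bonds, n_bits, radius)
  })
  if (scalar) fps[[1]] else fps
}

# monoisotopic neutral mass from the parsed graph (explicit atoms +
# inferred implicit hydrogens)
.mono_mass_from_graph <- function(elem, bonds) {
  m <- .MONO_MASS[elem]
  if (anyNA(m)) return(NA_real_)
  nbr_sum <- numeric(length(elem))
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      nbr_sum[bonds[r, 1]] <- nbr_sum[bonds[r, 1]] + bonds[r, 3]
      nbr_sum[bonds[r, 2]] <- nbr_sum[bonds[r, 2]] + bonds[r, 3]
    }
  }
  val <- .VALENCE[elem]
  hcnt <- pmax(0, ifelse(is.na(val), 0, val - nbr_sum))
  sum(m) + sum(hcnt) * .MONO_MASS[["H"]]
}

#' Extract the fingerprint matrix from a molecule table
#'
#' @param molecules A molecule tibble with a `fingerprint` list-column
#'   (as returned by [read_molecules()] or [gen_library()]).
#' @return A numeric 0/1 matrix, one row per molecule, with `mol_id`
#'   row names.
#' @export
fingerprint_matrix <- function(molecules) {
  stopifnot(is.data.frame(molecules), "fingerprint" %in% names(molecules))
  len <- lengths(molecules$fingerprint)
  if (length(unique(len)) > 1) {
    abort("inconsistent fingerprint lengths across molecules")
  }
  m <- do.call(rbind, molecules$fingerprint)
  storage.mode(m) <- "double"
  rownames(m) <- molecules$mol_id
  m
}
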