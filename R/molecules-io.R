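#' Read a molecule table from SDF, SMILES CSV or fingerprint CSV
#'
#' All three inputs produce the same tabular container used throughout the
#' package: one row per molecule with a `fingerprint` list-column. Records
#' that fail to parse are counted and reported with a warning, never
#' silently dropped. Retention times are in seconds, masses in Da.
#'
#' Accepted formats:
#' \describe{
#'   \item{`sdf`}{A V2000 SDF file; fingerprints and monoisotopic masses are
#'     computed from the structures.}
#'   \item{`smiles_csv`}{CSV with columns `mol_id`, `smiles` and optionally
#'     `rt_s`, `mono_mass`.}
#'   \item{`fp_csv`}{CSV with `mol_id`, optional `rt_s` / `mono_mass`, and
#'     one 0/1 column per fingerprint bit; structures absent.}
#' }
#'
#' @param path Path to the input file.
#' @param format One of `"auto"`, `"sdf"`, `"smiles_csv"`, `"fp_csv"`.
#' @param n_bits,radius Fingerprint parameters for structure inputs.
#' @return A tibble with columns `mol_id`, `smiles`, `fingerprint`
#'   (list-column), `mono_mass`, `rt_s`, carrying the number of unparseable
#'   records in the `"parse_failures"` attribute.
#' @export
read_molecules <- function(path, format = c("auto", "sdf", "smiles_csv", "fp_csv"),
                           n_bits = 1024, radius = 2) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else {
      hdr <- names(read.csv(path, nrows = 1, check.names = FALSE))
      if ("smiles" %in% hdr) "smiles_csv" else "fp_csv"
    }
  }
  out <- switch(format,
    sdf = .read_sdf(path, n_bits, radius),
    smiles_csv = .read_smiles_csv(path, n_bits, radius),
    fp_csv = .read_fp_csv(path)
  )
  if (nrow(out$records) == 0) abort(paste0("no valid molecule records in ", path))
  failures <- out$failures
  if (failures > 0) {
    warn(paste0(failures, " record(s) in ", path, " could not be parsed and were skipped"))
  }
  attr(out$records, "parse_failures") <- failures
  out$records
}

.read_sdf <- function(path, n_bits, radius) {
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    abort("ChemmineR is required to read SDF files")
  }
  # parse record by record so one malformed block cannot take down the
  # whole file; failures are counted per block
  lines <- readLines(path, warn = FALSE)
  ends <- grep("^\\$\\$\\$\\$\\s*$", lines)
  if (length(ends) == 0) ends <- length(lines)
  starts <- c(1, head(ends, -1) + 1)
  blocks <- purrr::map2(starts, ends, function(s, e) lines[s:e])
  blocks <- blocks[vapply(blocks, function(b) any(nzchar(trimws(b))), logical(1))]
  rows <- purrr::imap(blocks, function(b, i) {
    tryCatch({
      tmp <- tempfile(fileext = ".sdf")
      on.exit(unlink(tmp))
      writeLines(b, tmp)
      sdfs <- suppressWarnings(ChemmineR::read.SDFset(tmp))
      if (!suppressWarnings(ChemmineR::validSDF(sdfs))) return(NULL)
      id <- unname(ChemmineR::sdfid(sdfs))[1]
      if (is.na(id) || id == "") id <- paste0("mol_", i)
      g <- .sdf_graph(sdfs[[1]])
      list(id = id,
           fp = .fp_from_graph(g$elem, g$bonds, n_bits, radius),
           mass = .mono_mass_from_graph(g$elem, g$bonds))
    }, error = function(e) NULL)
  })
  bad <- purrr::map_lgl(rows, is.null)
  list(records = tibble(
    mol_id = purrr::map_chr(rows[!bad], "id"),
    smiles = NA_character_,
    fingerprint = purrr::map(rows[!bad], "fp"),
    mono_mass = purrr::map_dbl(rows[!bad], "mass"),
    rt_s = NA_real_
  ), failures = sum(bad))
}

.read_smiles_csv <- function(path, n_bits, radius) {
  df <- as_tibble(read.csv(path, check.names = FALSE, stringsAsFactors = FALSE))
  if (!all(c("mol_id", "smiles") %in% names(df))) {
    abort("smiles_csv must have columns `mol_id` and `smiles`")
  }
  rows <- purrr::map(df$smiles, function(s) {
    tryCatch({
      sdf <- .smiles_to_sdfset(s)
      g <- .sdf_graph(sdf[[1]])
      list(fp = .fp_from_graph(g$elem, g$bonds, n_bits, radius),
           mass = .mono_mass_from_graph(g$elem, g$bonds))
    }, error = function(e) NULL)
  })
  bad <- purrr::map_lgl(rows, is.null)
  list(records = tibble(
    mol_id = as.character(df$mol_id[!bad]),
    smiles = df$smiles[!bad],
    fingerprint = purrr::map(rows[!bad], "fp"),
    mono_mass = if ("mono_mass" %in% names(df)) df$mono_mass[!bad]
                else purrr::map_dbl(rows[!bad], "mass"),
    rt_s = if ("rt_s" %in% names(df)) df$rt_s[!bad] else NA_real_
  ), failures = sum(bad))
}

.read_fp_csv <- function(path) {
  df <- as_tibble(read.csv(path, check.names = FALSE, stringsAsFactors = FALSE))
  if (!"mol_id" %in% names(df)) abort("fp_csv must have a `mol_id` column")
  meta <- intersect(c("mol_id", "rt_s", "mono_mass"), names(df))
  bit_cols <- setdiff(names(df), meta)
  if (length(bit_cols) == 0) abort("fp_csv has no fingerprint bit columns")
  bits <- as.matrix(df[bit_cols])
  if (!all(bits %in% c(0, 1))) abort("fingerprint columns must be 0/1")
  list(records = tibble(
    mol_id = as.character(df$mol_id),
    smiles = NA_character_,
    fingerprint = lapply(seq_len(nrow(bits)), function(i) as.integer(bits[i, ])),
    mono_mass = if ("mono_mass" %in% names(df)) df$mono_mass else NA_real_,
    rt_s = if ("rt_s" %in% names(df)) df$rt_s else NA_real_
  ), failures = 0L)
}
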