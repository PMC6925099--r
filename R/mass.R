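# proton mass in Da; singly charged adducts only
.PROTON_MASS <- 1.007276

.normalize_adduct <- function(adduct) {
  a <- gsub("−", "-", adduct)  # unicode minus
  bad <- !a %in% c("M+H", "M-H")
  if (any(bad)) {
    abort(paste0("unknown adduct label(s): ", paste(unique(adduct[bad]), collapse = ", "),
                 " (supported: M+H, M-H)"))
  }
  a
}

#' Theoretical m/z of a singly charged adduct ion
#'
#' @param mono_mass Monoisotopic neutral mass in Da (vectorised).
#' @param adduct `"M+H"` (protonated) or `"M-H"` (deprotonated).
#' @return m/z in Da.
#' @examples
#' adduct_mz(100, "M+H")  # 101.007276
#' @export
adduct_mz <- function(mono_mass, adduct) {
  stopifnot(is.numeric(mono_mass))
  if (any(mono_mass <= 0)) abort("`mono_mass` must be positive")
  a <- .normalize_adduct(adduct)
  mono_mass + ifelse(a == "M+H", .PROTON_MASS, -.PROTON_MASS)
}

#' Accurate-mass match within a ppm tolerance
#'
#' The relative deviation is taken against the theoretical ion m/z, the
#' convention of database accurate-mass search; a deviation exactly at the
#' tolerance counts as a match.
#'
#' @param obs_mz,theo_mz Observed and theoretical m/z in Da (vectorised).
#' @param tol_ppm Tolerance in parts per million.
#' @return Logical vector.
#' @export
ppm_match <- function(obs_mz, theo_mz, tol_ppm) {
  stopifnot(is.numeric(obs_mz), is.numeric(theo_mz), tol_ppm >= 0)
  if (any(obs_mz <= 0) || any(theo_mz <= 0)) abort("masses must be positive")
  1e6 * abs(obs_mz - theo_mz) / theo_mz <= tol_ppm
}
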