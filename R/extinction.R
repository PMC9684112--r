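# Compiled molar extinction coefficients of oxy- and deoxy-hemoglobin
# (cm^-1 M^-1) at the five excitation wavelengths, from the standard
# compiled literature tabulation of hemoglobin absorption spectra.
# Only ratios across wavelengths matter downstream: concentrations are
# treated as relative units throughout.
.hbExtinction <- data.frame(
  wavelengthNm = c(700, 730, 755, 800, 850),
  epsHbO = c(290.0, 390.0, 530.6, 816.0, 1058.0),
  epsHbR = c(1794.28, 1102.20, 1548.52, 761.72, 691.32)
)

#' Hemoglobin extinction table
#'
#' Molar extinction coefficients of oxygenated (HbO) and deoxygenated (HbR)
#' hemoglobin at the requested excitation wavelengths, taken from the
#' compiled literature spectra shipped with the package. The condition
#' number of the resulting wavelengths-by-2 unmixing system is attached as
#' attribute \code{"conditionNumber"}.
#'
#' @param wavelengthsNm wavelengths to tabulate; must be among the shipped
#'   700, 730, 755, 800, 850 nm.
#' @return data.frame with columns wavelengthNm, epsHbO, epsHbR
#'   (cm^-1 M^-1).
#' @examples
#' extinctionTable(c(700, 800, 850))
#' @export
extinctionTable <- function(wavelengthsNm = .hbExtinction$wavelengthNm) {
  idx <- match(wavelengthsNm, .hbExtinction$wavelengthNm)
  if (anyNA(idx))
    stop("no tabulated extinction at wavelength(s): ",
         paste(wavelengthsNm[is.na(idx)], collapse = ", "), " nm")
  tab <- .hbExtinction[idx, , drop = FALSE]
  rownames(tab) <- NULL
  E <- as.matrix(tab[, c("epsHbO", "epsHbR")])
  attr(tab, "conditionNumber") <- kappa(E, exact = TRUE)
  tab
}

#' Absorption coefficients of a hemoglobin mixture
#'
#' Relative optical absorption at the given wavelengths of blood with total
#' hemoglobin \code{hbt} (relative units) and oxygen saturation \code{so2}.
#'
#' @param so2 oxygen saturation in [0, 1].
#' @param hbt total hemoglobin (relative units).
#' @param wavelengthsNm wavelengths at which to evaluate.
#' @return numeric vector of absorption values per wavelength.
#' @export
hemoglobinAbsorption <- function(so2, hbt = 1,
                                 wavelengthsNm = .hbExtinction$wavelengthNm) {
  stopifnot(so2 >= 0, so2 <= 1, hbt >= 0)
  tab <- extinctionTable(wavelengthsNm)
  log(10) * hbt * (tab$epsHbO * so2 + tab$epsHbR * (1 - so2)) / 1000
}
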