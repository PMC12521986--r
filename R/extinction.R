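# Molar extinction coefficients of oxy- and deoxyhaemoglobin, expressed
# per micromolar and per cm with the natural-log convention (values are
# the conventional base-10 molar coefficients in cm^-1 M^-1 scaled by
# ln(10) / 1e6).  Only the wavelengths used by common CW devices are
# tabulated; the forward model and the Beer-Lambert inversion share this
# table, so the convention cancels in round trips.
.extinction_table <- data.frame(
  wavelength = c(690, 750, 760, 780, 800, 830, 850),
  hbo = c(276, 518, 586, 710, 816, 974, 1058) * log(10) / 1e6,
  hbr = c(2051.96, 1405.24, 1548.52, 1075.44, 761.72, 693.04, 691.32) *
    log(10) / 1e6
)

#' Extinction coefficients for a pair of wavelengths
#'
#' Returns the 2 x 2 matrix `E` with rows indexed by wavelength and
#' columns by chromophore (HbO, HbR), in units of OD per micromolar per
#' cm (natural-log convention), used by both the forward intensity model
#' and the modified Beer-Lambert inversion.
#'
#' @param wavelengths Two wavelengths in nm; must be tabulated.
#' @return A 2 x 2 numeric matrix with dimnames.
#' @export
extinction_coefficients <- function(wavelengths) {
  idx <- match(wavelengths, .extinction_table$wavelength)
  if (anyNA(idx))
    stopf("no extinction coefficients tabulated for wavelength(s): %s",
          paste(wavelengths[is.na(idx)], collapse = ", "))
  E <- as.matrix(.extinction_table[idx, c("hbo", "hbr")])
  dimnames(E) <- list(paste0(wavelengths, "nm"), c("hbo", "hbr"))
  E
}
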