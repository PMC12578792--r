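#' Load hemoglobin molar extinction coefficients
#'
#' Reads the packaged extinction-coefficient table (after the standard
#' Gratzer/Prahl-style compilations; units cm^-1 per mol/L) and linearly
#' interpolates to the requested wavelengths. The same table drives both the
#' synthetic optical forward projection and the modified Beer-Lambert
#' inversion, so the two are consistent by construction.
#'
#' @param wavelengths_nm Wavelengths to interpolate to (default 763, 841 nm).
#' @param path Optional path to an alternative TSV with columns
#'   `wavelength_nm`, `eps_hbo`, `eps_hbr`.
#' @return A 2-column matrix (`eps_hbo`, `eps_hbr`) with one row per
#'   wavelength, in cm^-1 M^-1.
#' @export
extinction_coefficients <- function(wavelengths_nm = c(763, 841), path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "extinction_coefficients.tsv",
                        package = "natfnirs", mustWork = TRUE)
  }
  tab <- utils::read.delim(path, sep = "\t")
  assert_that(all(c("wavelength_nm", "eps_hbo", "eps_hbr") %in% names(tab)),
              "extinction table must have columns wavelength_nm, eps_hbo, eps_hbr")
  rng <- range(tab$wavelength_nm)
  assert_that(all(wavelengths_nm >= rng[1] & wavelengths_nm <= rng[2]),
              "requested wavelength outside the tabulated range [%g, %g] nm",
              rng[1], rng[2])
  e <- cbind(
    eps_hbo = stats::approx(tab$wavelength_nm, tab$eps_hbo, wavelengths_nm)$y,
    eps_hbr = stats::approx(tab$wavelength_nm, tab$eps_hbr, wavelengths_nm)$y
  )
  rownames(e) <- as.character(wavelengths_nm)
  e
}
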