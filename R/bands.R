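# Spectral band primitives shared by the synthetic-data generator.

# Bi-Gaussian profile: unit height at `peak`, distinct left/right widths.
# sigma_left = sigma * (1 - asym), sigma_right = sigma * (1 + asym), so the
# mode sits exactly at `peak` and asym = 0 gives a symmetric Gaussian.
bigauss <- function(x, peak, fwhm, asym = 0) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  s <- ifelse(x < peak, sigma * (1 - asym), sigma * (1 + asym))
  exp(-(x - peak)^2 / (2 * s^2))
}

#' Describe an emission band shape
#'
#' Bi-Gaussian emission profile used by the synthetic generator: unit
#' height at `peak_nm`, full width at half maximum `width_nm`, and an
#' `asymmetry` in `(-1, 1)` that widens the red side for positive values
#' (fluorophore emission bands have red tails). `amplitude_per_nM` sets
#' the peak intensity contributed per nM of emitting species; it folds in
#' quantum yield and instrument gain.
#'
#' @param peak_nm emission maximum in nm.
#' @param width_nm full width at half maximum in nm (> 0).
#' @param asymmetry tail-skew parameter in `(-1, 1)`; 0 is symmetric.
#' @param amplitude_per_nM RFU per nM at the band peak (> 0).
#' @return object of class `band_shape`.
#' @export
band_shape <- function(peak_nm, width_nm, asymmetry = 0, amplitude_per_nM = 1) {
  if (width_nm <= 0) fq_validation_error("width_nm must be > 0")
  if (amplitude_per_nM <= 0) fq_validation_error("amplitude_per_nM must be > 0")
  if (abs(asymmetry) >= 1) fq_validation_error("asymmetry must lie in (-1, 1)")
  structure(list(peak_nm = peak_nm, width_nm = width_nm,
                 asymmetry = asymmetry, amplitude_per_nM = amplitude_per_nM),
            class = "band_shape")
}

band_values <- function(shape, grid_nm) {
  bigauss(grid_nm, shape$peak_nm, shape$width_nm, shape$asymmetry)
}

#' Generate one synthetic emission band
#'
#' @param shape a [band_shape()].
#' @param conc_nM concentration of the emitting species; intensities are
#'   exactly linear in it.
#' @param grid_nm wavelength grid; must cover `peak_nm` plus/minus three
#'   band widths so the band is not truncated.
#' @param well_id,excitation_nm metadata for the produced spectrum.
#' @return an [emission_spectrum()].
#' @export
emission_band <- function(shape, conc_nM, grid_nm, well_id = "SIM",
                          excitation_nm = 470) {
  if (conc_nM < 0) fq_validation_error("conc_nM must be >= 0")
  if (grid_nm[1L] > shape$peak_nm - 3 * shape$width_nm ||
      grid_nm[length(grid_nm)] < shape$peak_nm + 3 * shape$width_nm)
    fq_range_error("grid too narrow: must cover peak +/- 3 band widths")
  emission_spectrum(well_id, excitation_nm, grid_nm,
                    shape$amplitude_per_nM * conc_nM * band_values(shape, grid_nm))
}
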