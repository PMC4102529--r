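#' Construct a single-well emission spectrum
#'
#' One wavelength-resolved fluorescence emission scan of one well, together
#' with the acquisition metadata (excitation wavelength, gain, bandwidths,
#' integration time) that downstream stages carry through unchanged.
#'
#' @param well_id plate coordinate, e.g. `"A1"`.
#' @param excitation_nm excitation wavelength in nm (> 0).
#' @param wavelengths strictly increasing emission wavelength grid in nm.
#' @param intensities relative fluorescence units (RFU); same length as
#'   `wavelengths`. Negative values are permitted (they arise after
#'   background subtraction) but must be finite.
#' @param gain instrument gain (metadata).
#' @param ex_bandwidth_nm,em_bandwidth_nm excitation/emission bandwidths in
#'   nm (metadata).
#' @param integration_time_us integration time in microseconds (metadata).
#' @return an object of class `emission_spectrum`.
#' @export
emission_spectrum <- function(well_id, excitation_nm, wavelengths, intensities,
                              gain = NA_real_, ex_bandwidth_nm = NA_real_,
                              em_bandwidth_nm = NA_real_,
                              integration_time_us = NA_real_) {
  wavelengths <- as.numeric(wavelengths)
  intensities <- as.numeric(intensities)
  if (length(wavelengths) != length(intensities))
    fq_validation_error("wavelengths and intensities must have equal length")
  if (length(wavelengths) < 2L)
    fq_validation_error("a spectrum needs at least two grid points")
  if (any(diff(wavelengths) <= 0))
    fq_validation_error("wavelength grid must be strictly increasing")
  if (!is.numeric(excitation_nm) || length(excitation_nm) != 1L ||
      !is.finite(excitation_nm) || excitation_nm <= 0)
    fq_validation_error("excitation_nm must be a single positive number")
  if (any(!is.finite(intensities)))
    fq_validation_error("intensities must be finite")
  structure(
    list(well_id = as.character(well_id), excitation_nm = excitation_nm,
         wavelengths = wavelengths, intensities = intensities,
         gain = gain, ex_bandwidth_nm = ex_bandwidth_nm,
         em_bandwidth_nm = em_bandwidth_nm,
         integration_time_us = integration_time_us),
    class = "emission_spectrum")
}

#' @export
print.emission_spectrum <- function(x, ...) {
  cat(sprintf(
    "<emission_spectrum> well %s, ex %g nm, %d points (%g-%g nm), gain %s\n",
    x$well_id, x$excitation_nm, length(x$wavelengths),
    min(x$wavelengths), max(x$wavelengths),
    ifelse(is.na(x$gain), "?", format(x$gain))))
  invisible(x)
}

#' Construct a UV-visible absorbance spectrum
#'
#' @param wavelengths strictly increasing wavelength grid in nm.
#' @param absorbance optical density (dimensionless), same length.
#' @param pathlength_cm cuvette path length in cm.
#' @return an object of class `absorbance_spectrum`.
#' @export
absorbance_spectrum <- function(wavelengths, absorbance, pathlength_cm = 1) {
  wavelengths <- as.numeric(wavelengths)
  absorbance <- as.numeric(absorbance)
  if (length(wavelengths) != length(absorbance))
    fq_validation_error("wavelengths and absorbance must have equal length")
  if (any(diff(wavelengths) <= 0))
    fq_validation_error("wavelength grid must be strictly increasing")
  if (any(!is.finite(absorbance)))
    fq_validation_error("absorbance must be finite")
  if (!is.finite(pathlength_cm) || pathlength_cm <= 0)
    fq_validation_error("pathlength_cm must be positive")
  structure(list(wavelengths = wavelengths, absorbance = absorbance,
                 pathlength_cm = pathlength_cm),
            class = "absorbance_spectrum")
}

#' @export
print.absorbance_spectrum <- function(x, ...) {
  cat(sprintf("<absorbance_spectrum> %d points (%g-%g nm), path %g cm\n",
              length(x$wavelengths), min(x$wavelengths), max(x$wavelengths),
              x$pathlength_cm))
  invisible(x)
}

same_grid <- function(a, b) {
  length(a$wavelengths) == length(b$wavelengths) &&
    all(a$wavelengths == b$wavelengths)
}

#' Subtract a blank (background) scan from a spectrum
#'
#' Pointwise difference on identical wavelength grids; the metadata of `s`
#' is preserved. No interpolation is ever attempted: a grid mismatch is an
#' error, because silently resampling hides acquisition mistakes. The
#' result may contain small negative intensities; these are retained so
#' that downstream decomposition arithmetic stays unbiased.
#'
#' @param s an [emission_spectrum()].
#' @param blank an [emission_spectrum()] on the identical grid and
#'   excitation wavelength.
#' @return an `emission_spectrum` with `blank` subtracted.
#' @export
subtract_background <- function(s, blank) {
  if (!same_grid(s, blank))
    fq_validation_error("spectrum and blank are on different wavelength grids")
  if (s$excitation_nm != blank$excitation_nm)
    fq_validation_error("spectrum and blank have different excitation wavelengths")
  out <- s
  out$intensities <- s$intensities - blank$intensities
  out
}

#' Average replicate emission scans
#'
#' Pointwise mean and pointwise root-mean-square deviation about the mean,
#' across replicate scans of the same condition (e.g. 9 repeated
#' measurements from 3 samples read 3 times each).
#'
#' @param scans list of at least two [emission_spectrum()] objects on
#'   identical grids and excitation.
#' @return list with `mean` (an `emission_spectrum`, metadata from the
#'   first scan) and `rms` (numeric vector, per-wavelength rms deviation).
#' @export
average_replicates <- function(scans) {
  if (!is.list(scans) || length(scans) < 2L)
    fq_validation_error("need at least two replicate scans")
  first <- scans[[1L]]
  for (s in scans[-1L]) {
    if (!same_grid(first, s))
      fq_validation_error("replicate scans are on different wavelength grids")
    if (s$excitation_nm != first$excitation_nm)
      fq_validation_error("replicate scans mix excitation wavelengths")
  }
  m <- vapply(scans, function(s) s$intensities, numeric(length(first$wavelengths)))
  mu <- rowMeans(m)
  rms <- sqrt(rowMeans((m - mu)^2))
  out <- first
  out$intensities <- mu
  list(mean = out, rms = rms)
}

# Linear interpolation of a spectrum at arbitrary wavelengths (within span).
interp_intensity <- function(s, at_nm) {
  stats::approx(s$wavelengths, s$intensities, xout = at_nm, rule = 1)$y
}

check_window <- function(s, lo, hi, what = "window") {
  if (lo > hi) fq_range_error(sprintf("%s has lo > hi", what))
  if (lo < s$wavelengths[1L] || hi > s$wavelengths[length(s$wavelengths)])
    fq_range_error(sprintf("%s [%g, %g] nm lies outside the grid span [%g, %g] nm",
                           what, lo, hi, s$wavelengths[1L],
                           s$wavelengths[length(s$wavelengths)]))
}

#' Trapezoidal band integral of an emission spectrum
#'
#' Integrates intensity over the closed window `[lo_nm, hi_nm]` by the
#' trapezoidal rule. Window endpoints that do not fall on the grid are
#' obtained by linear interpolation, so the integral is exactly additive
#' over adjacent windows.
#'
#' @param s an [emission_spectrum()].
#' @param lo_nm,hi_nm integration window in nm, inside the grid span.
#' @return integrated intensity in RFU·nm.
#' @export
integrate_band <- function(s, lo_nm, hi_nm) {
  check_window(s, lo_nm, hi_nm, "integration window")
  if (lo_nm == hi_nm) return(0)
  inside <- s$wavelengths > lo_nm & s$wavelengths < hi_nm
  x <- c(lo_nm, s$wavelengths[inside], hi_nm)
  y <- c(interp_intensity(s, lo_nm), s$intensities[inside],
         interp_intensity(s, hi_nm))
  pracma::trapz(x, y)
}

#' Peak intensity as a narrow window mean
#'
#' Mean intensity over `[center - halfwidth, center + halfwidth]`
#' (trapezoid-weighted), the package's convention for reading "the
#' intensity at 520 nm" or "at 570 nm" robustly against 1-2 nm grid
#' offsets. With `halfwidth_nm = 0` the linearly interpolated value at
#' `center_nm` is returned.
#'
#' @param s an [emission_spectrum()].
#' @param center_nm window center in nm.
#' @param halfwidth_nm half-width of the averaging window in nm
#'   (default 2).
#' @return intensity in RFU.
#' @export
peak_intensity <- function(s, center_nm, halfwidth_nm = 2) {
  if (halfwidth_nm < 0) fq_range_error("halfwidth_nm must be >= 0")
  lo <- center_nm - halfwidth_nm
  hi <- center_nm + halfwidth_nm
  check_window(s, lo, hi, "peak window")
  if (halfwidth_nm == 0) return(interp_intensity(s, center_nm))
  integrate_band(s, lo, hi) / (hi - lo)
}

# Absorbance read at a single wavelength (linear interpolation).
absorbance_at <- function(abs, at_nm) {
  w <- abs$wavelengths
  if (at_nm < w[1L] || at_nm > w[length(w)])
    fq_range_error(sprintf("absorbance spectrum does not cover %g nm", at_nm))
  stats::approx(w, abs$absorbance, xout = at_nm, rule = 1)$y
}
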