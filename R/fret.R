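#' Analysis windows and excitation settings
#'
#' Collects the spectral read-out conventions used across the pipeline:
#' where the donor and acceptor peaks are read, the averaging half-width,
#' the sensitized-emission integration window, and the two excitation
#' wavelengths. The acceptor excitation default is 530 nm; plate metadata
#' or configuration may override it (instruments are operated anywhere in
#' the acceptor band, e.g. 530 or 540 nm), and the configured value is
#' authoritative.
#'
#' @param donor_peak_nm,acceptor_peak_nm peak read-out centers in nm.
#' @param peak_halfwidth_nm half-width of the peak averaging window
#'   (see [peak_intensity()]).
#' @param integral_lo_nm,integral_hi_nm sensitized-emission integration
#'   window in nm.
#' @param donor_ex_nm,acceptor_ex_nm excitation wavelengths in nm.
#' @return a list of class `analysis_windows`.
#' @export
analysis_windows <- function(donor_peak_nm = 520, acceptor_peak_nm = 570,
                             peak_halfwidth_nm = 2, integral_lo_nm = 560,
                             integral_hi_nm = 610, donor_ex_nm = 470,
                             acceptor_ex_nm = 530) {
  if (integral_lo_nm >= integral_hi_nm)
    fq_validation_error("integration window must have lo < hi")
  structure(list(donor_peak_nm = donor_peak_nm,
                 acceptor_peak_nm = acceptor_peak_nm,
                 peak_halfwidth_nm = peak_halfwidth_nm,
                 integral_lo_nm = integral_lo_nm,
                 integral_hi_nm = integral_hi_nm,
                 donor_ex_nm = donor_ex_nm, acceptor_ex_nm = acceptor_ex_nm),
            class = "analysis_windows")
}

#' Bundle the two cross-talk ratio factors
#'
#' @param a donor bleed-through factor: donor-only emission at the
#'   acceptor peak divided by its emission at the donor peak, under donor
#'   excitation.
#' @param b acceptor direct-excitation factor: acceptor-only emission at
#'   the acceptor peak under donor excitation divided by the same reading
#'   under acceptor-band excitation.
#' @param a_rms,b_rms spread of each factor across the calibration
#'   concentration series.
#' @param n_a,n_b number of calibration conditions averaged.
#' @return a list of class `ratio_factors`.
#' @export
ratio_factors <- function(a, b, a_rms = 0, b_rms = 0, n_a = NA_integer_,
                          n_b = NA_integer_) {
  if (a < 0 || a >= 1)
    fq_validation_error("ratio factor a must lie in [0, 1)")
  if (b < 0 || b >= 1)
    fq_validation_error("ratio factor b must lie in [0, 1)")
  if (a_rms < 0 || b_rms < 0) fq_validation_error("rms must be >= 0")
  structure(list(a = a, b = b, a_rms = a_rms, b_rms = b_rms,
                 n_a = n_a, n_b = n_b), class = "ratio_factors")
}

#' @export
print.ratio_factors <- function(x, ...) {
  cat(sprintf("<ratio_factors> a = %.4f +/- %.4f (n=%s), b = %.4f +/- %.4f (n=%s)\n",
              x$a, x$a_rms, x$n_a, x$b, x$b_rms, x$n_b))
  invisible(x)
}

#' Donor bleed-through ratio factor a
#'
#' For each donor-only calibration spectrum (donor excitation), the ratio
#' of the emission intensity at the acceptor peak to that at the donor
#' peak is computed; the factor is the mean across the concentration
#' series and the quoted uncertainty its rms. The ratio is invariant
#' under intensity scaling, so any set of donor concentrations with
#' resolvable peaks can serve as calibration.
#'
#' @param donor_only list of donor-only [emission_spectrum()] under donor
#'   excitation (one or more concentrations).
#' @param windows an [analysis_windows()].
#' @return list with `a`, `rms`, `per_spectrum`, `n`.
#' @export
ratio_factor_a <- function(donor_only, windows = analysis_windows()) {
  if (!is.list(donor_only) || length(donor_only) < 1L)
    fq_validation_error("need at least one donor-only spectrum")
  per <- vapply(donor_only, function(s) {
    i520 <- peak_intensity(s, windows$donor_peak_nm, windows$peak_halfwidth_nm)
    i570 <- peak_intensity(s, windows$acceptor_peak_nm, windows$peak_halfwidth_nm)
    if (i520 <= 0)
      fq_degenerate_error("donor-only spectrum has no resolvable donor peak")
    i570 / i520
  }, 0)
  list(a = mean(per), rms = sqrt(mean((per - mean(per))^2)),
       per_spectrum = per, n = length(per))
}

#' Acceptor direct-excitation ratio factor b
#'
#' For a matched concentration series of acceptor-only wells scanned under
#' both excitations, the per-concentration ratio of the acceptor-peak
#' intensity under donor excitation to that under acceptor-band
#' excitation; b is the mean across the series, with its rms.
#'
#' @param acceptor_only_ex470 acceptor-only spectra under donor
#'   excitation, one per concentration.
#' @param acceptor_only_exA matched spectra under acceptor-band
#'   excitation (same order, same concentrations).
#' @param windows an [analysis_windows()].
#' @return list with `b`, `rms`, `per_spectrum`, `n`.
#' @export
ratio_factor_b <- function(acceptor_only_ex470, acceptor_only_exA,
                           windows = analysis_windows()) {
  if (length(acceptor_only_ex470) != length(acceptor_only_exA))
    fq_validation_error("acceptor-only series under the two excitations differ in length")
  if (length(acceptor_only_ex470) < 1L)
    fq_validation_error("need at least one acceptor-only concentration")
  per <- mapply(function(s470, sA) {
    num <- peak_intensity(s470, windows$acceptor_peak_nm, windows$peak_halfwidth_nm)
    den <- peak_intensity(sA, windows$acceptor_peak_nm, windows$peak_halfwidth_nm)
    if (den <= 0)
      fq_degenerate_error("acceptor-only spectrum has no direct-excitation signal")
    num / den
  }, acceptor_only_ex470, acceptor_only_exA)
  b <- mean(per)
  if (b >= 1)
    warning("ratio factor b >= 1: direct-excitation reference looks degenerate",
            call. = FALSE)
  list(b = b, rms = sqrt(mean((per - b)^2)), per_spectrum = per,
       n = length(per))
}

#' Extract the FRET emission signal at the acceptor peak
#'
#' Decomposes the total mixture intensity at the acceptor emission peak
#' (donor excitation) into donor bleed-through, direct acceptor emission
#' and sensitized emission:
#' `F_FRET = F_DA - a * F_D - b * F_A`.
#' Negative results (possible at zero acceptor or from noise) are
#' returned as-is; clipping to zero would bias downstream least-squares
#' fits and is applied only when reporting.
#'
#' @param F_DA total mixture intensity at the acceptor peak, donor
#'   excitation (RFU).
#' @param F_D mixture intensity at the donor peak, donor excitation
#'   (RFU); the unquenched-donor reading used to scale bleed-through.
#' @param F_A mixture intensity at the acceptor peak under acceptor-band
#'   excitation (RFU).
#' @param factors a [ratio_factors()].
#' @return the FRET emission signal in RFU.
#' @export
fret_signal <- function(F_DA, F_D, F_A, factors) {
  if (any(!is.finite(c(F_DA, F_D, F_A))))
    fq_validation_error("intensities must be finite")
  F_DA - factors$a * F_D - factors$b * F_A
}

#' Cross-talk-corrected FRET efficiency from spectral integrals
#'
#' Sensitized-emission estimator over the integration window (560-610 nm
#' by default) under donor excitation. The donor bleed contribution is
#' removed by scaling the donor-only reference to the mixture's
#' donor-peak reading; the direct acceptor contribution is removed by
#' subtracting the acceptor-only scan under donor excitation. The
#' residual sensitized integral is normalized by the acceptor's direct
#' emission and by the absorbance ratio:
#' `E = 100 * (A_A / A_D) * S / I_A`, with
#' `S = integral(f_mix - s_D * f_donor - f_acc470)` and
#' `I_A = integral(f_acc470)`.
#'
#' This estimator is deliberately isolated here so the algebra can be
#' swapped without touching callers; it is the package's versioned
#' reconstruction of the cited sensitized-emission method.
#'
#' @param mix_ex470 mixture spectrum, donor excitation.
#' @param donor_only_ex470 donor-only reference at the mixture's donor
#'   concentration, donor excitation.
#' @param acceptor_only_ex470 acceptor-only reference at the mixture's
#'   acceptor concentration, donor excitation.
#' @param acceptor_only_exA acceptor-only reference under acceptor-band
#'   excitation (diagnostic; optional, used to sanity-check the direct
#'   reference).
#' @param A_D,A_A absorbances of donor and acceptor at the donor
#'   excitation wavelength.
#' @param windows an [analysis_windows()].
#' @return list of class `efficiency_result` with `E_pct`,
#'   `sen_integral`, `acc_integral`, `A_D`, `A_A`, `donor_scale`.
#' @export
fret_efficiency <- function(mix_ex470, donor_only_ex470, acceptor_only_ex470,
                            acceptor_only_exA = NULL, A_D, A_A,
                            windows = analysis_windows()) {
  if (!is.finite(A_D) || A_D <= 0)
    fq_validation_error("A_D must be a positive absorbance")
  if (!is.finite(A_A) || A_A < 0)
    fq_validation_error("A_A must be a non-negative absorbance")
  lo <- windows$integral_lo_nm; hi <- windows$integral_hi_nm

  don_peak_mix <- peak_intensity(mix_ex470, windows$donor_peak_nm,
                                 windows$peak_halfwidth_nm)
  don_peak_ref <- peak_intensity(donor_only_ex470, windows$donor_peak_nm,
                                 windows$peak_halfwidth_nm)
  if (don_peak_ref <= 0)
    fq_degenerate_error("donor-only reference has no donor-peak signal")
  s_d <- don_peak_mix / don_peak_ref

  acc_integral <- integrate_band(acceptor_only_ex470, lo, hi)
  if (acc_integral <= 0)
    fq_degenerate_error("acceptor direct-emission integral is <= 0")

  sen <- integrate_band(mix_ex470, lo, hi) -
    s_d * integrate_band(donor_only_ex470, lo, hi) -
    acc_integral
  e <- 100 * (A_A / A_D) * sen / acc_integral
  structure(list(E_pct = e, sen_integral = sen, acc_integral = acc_integral,
                 A_D = A_D, A_A = A_A, donor_scale = s_d),
            class = "efficiency_result")
}

#' @export
print.efficiency_result <- function(x, ...) {
  cat(sprintf("<efficiency_result> E = %.2f%% (sensitized %.4g, direct %.4g, A_A/A_D = %.4g)\n",
              x$E_pct, x$sen_integral, x$acc_integral, x$A_A / x$A_D))
  invisible(x)
}

#' Clip an efficiency (or any percentage) for reporting
#'
#' Estimators in this package keep negative and >100 values so that
#' averaging and fitting stay unbiased; reports clip to `[0, 100]`.
#'
#' @param pct numeric vector of percentages.
#' @return clipped values.
#' @export
clip_pct <- function(pct) pmin(pmax(pct, 0), 100)
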