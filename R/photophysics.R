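#' Fluorophore photophysical parameters
#'
#' Vendor-style dye constants used for degree-of-labeling and absorbance
#' calculations. Defaults for an Alexa-Fluor-488-like donor and an
#' Alexa-Fluor-555-like acceptor ship as an editable configuration file
#' (`system.file("extdata", "fluorophores.tsv", package = "fretquant")`);
#' nothing is hard-coded in the computations, so user-supplied constants
#' reproduce user results.
#'
#' @param name dye identifier.
#' @param ex_max_nm,em_max_nm absorbance and emission maxima in nm.
#' @param extinction_at_max molar extinction coefficient at the absorbance
#'   maximum, in M^-1 cm^-1.
#' @param quantum_yield fluorescence quantum yield in `[0, 1]`.
#' @param a280_correction fraction of the dye's peak absorbance that
#'   appears at 280 nm (protein-channel bleed), in `[0, 1)`.
#' @param abs_fwhm_nm,abs_asymmetry width and asymmetry of the dye's
#'   absorbance band (bi-Gaussian model; negative asymmetry widens the
#'   blue side), used when a relative absorbance at an off-peak
#'   wavelength is needed.
#' @return an object of class `fluorophore_params`.
#' @export
fluorophore_params <- function(name, ex_max_nm, em_max_nm, extinction_at_max,
                               quantum_yield, a280_correction = 0,
                               abs_fwhm_nm = 60, abs_asymmetry = -0.1) {
  if (extinction_at_max <= 0)
    fq_validation_error("extinction_at_max must be > 0")
  if (quantum_yield < 0 || quantum_yield > 1)
    fq_validation_error("quantum_yield must lie in [0, 1]")
  if (a280_correction < 0 || a280_correction >= 1)
    fq_validation_error("a280_correction must lie in [0, 1)")
  structure(list(name = name, ex_max_nm = ex_max_nm, em_max_nm = em_max_nm,
                 extinction_at_max = extinction_at_max,
                 quantum_yield = quantum_yield,
                 a280_correction = a280_correction,
                 abs_fwhm_nm = abs_fwhm_nm, abs_asymmetry = abs_asymmetry),
            class = "fluorophore_params")
}

#' @export
print.fluorophore_params <- function(x, ...) {
  cat(sprintf("<fluorophore_params> %s: ex %g nm, em %g nm, eps %g, QY %g\n",
              x$name, x$ex_max_nm, x$em_max_nm, x$extinction_at_max,
              x$quantum_yield))
  invisible(x)
}

#' Load fluorophore parameters from a configuration file
#'
#' @param path tab-separated file with one row per dye and the
#'   [fluorophore_params()] fields as columns; defaults to the
#'   configuration shipped with the package.
#' @return named list of [fluorophore_params()].
#' @export
read_fluorophore_params <- function(path = NULL) {
  path <- path %||% system.file("extdata", "fluorophores.tsv",
                                package = "fretquant", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i)
    fluorophore_params(tab$name[i], tab$ex_max_nm[i], tab$em_max_nm[i],
                       tab$extinction_at_max[i], tab$quantum_yield[i],
                       tab$a280_correction[i], tab$abs_fwhm_nm[i],
                       tab$abs_asymmetry[i]))
  names(out) <- tab$name
  out
}

# Relative absorbance of the dye at `at_nm` (1 at ex_max), bi-Gaussian band.
fluor_rel_absorbance <- function(fluor, at_nm) {
  bigauss(at_nm, fluor$ex_max_nm, fluor$abs_fwhm_nm, fluor$abs_asymmetry)
}

# Peak absorbance of the conjugate near the dye's absorbance maximum;
# the maximum within +/- 5 nm tolerates conjugation-induced shifts.
conjugate_amax <- function(abs, fluor, search_halfwidth_nm = 5) {
  w <- abs$wavelengths
  lo <- fluor$ex_max_nm - search_halfwidth_nm
  hi <- fluor$ex_max_nm + search_halfwidth_nm
  if (hi < w[1L] || lo > w[length(w)])
    fq_range_error(sprintf(
      "absorbance spectrum does not cover the dye maximum near %g nm",
      fluor$ex_max_nm))
  sel <- w >= lo & w <= hi
  if (!any(sel)) fq_range_error("no grid points near the dye maximum")
  max(abs$absorbance[sel])
}

#' Protein concentration from conjugate absorbance
#'
#' Beer-Lambert at 280 nm with the dye's 280-nm bleed subtracted:
#' `[protein] = (A280 - a280_correction * Amax) / (eps280 * pathlength)`.
#'
#' @param abs an [absorbance_spectrum()] of the conjugate covering 280 nm
#'   and the dye maximum.
#' @param fluor [fluorophore_params()] of the conjugated dye.
#' @param protein_eps280 protein molar extinction coefficient at 280 nm,
#'   M^-1 cm^-1.
#' @return molar protein concentration (M).
#' @export
protein_concentration <- function(abs, fluor, protein_eps280) {
  if (protein_eps280 <= 0) fq_validation_error("protein_eps280 must be > 0")
  a280 <- absorbance_at(abs, 280)
  amax <- conjugate_amax(abs, fluor)
  corrected <- a280 - fluor$a280_correction * amax
  if (corrected <= 0)
    fq_degenerate_error(
      "corrected A280 <= 0: the 280-nm absorbance is fully explained by dye bleed")
  corrected / (protein_eps280 * abs$pathlength_cm)
}

#' Specify a fluorophore-protein conjugate
#'
#' @param protein_id identifier of the labeled protein.
#' @param fluorophore [fluorophore_params()] of the conjugated dye.
#' @param absorbance an [absorbance_spectrum()] or a list of replicate
#'   scans of the conjugate.
#' @param protein_eps280 protein extinction coefficient at 280 nm.
#' @param protein_conc_M optional molar protein concentration; when `NULL`
#'   it is determined per scan via [protein_concentration()].
#' @return an object of class `conjugate_spec`.
#' @export
conjugate_spec <- function(protein_id, fluorophore, absorbance,
                           protein_eps280, protein_conc_M = NULL) {
  scans <- if (inherits(absorbance, "absorbance_spectrum")) list(absorbance)
           else absorbance
  if (!length(scans) || !all(vapply(scans, inherits, TRUE, "absorbance_spectrum")))
    fq_validation_error("absorbance must be (a list of) absorbance_spectrum")
  if (!is.null(protein_conc_M) && protein_conc_M <= 0)
    fq_validation_error("protein_conc_M must be > 0")
  structure(list(protein_id = protein_id, fluorophore = fluorophore,
                 scans = scans, protein_eps280 = protein_eps280,
                 protein_conc_M = protein_conc_M),
            class = "conjugate_spec")
}

#' Fluorophore-to-protein molar ratio (degree of labeling)
#'
#' `F/P = Amax / (eps_fluorophore * pathlength * [protein])`, with `Amax`
#' the conjugate absorbance at the dye maximum. When the conjugate carries
#' replicate absorbance scans the ratio is computed per scan and the rms
#' across scans is reported as its uncertainty.
#'
#' @param conjugate a [conjugate_spec()].
#' @return list with `ratio` (mean F/P), `rms` (across replicate scans;
#'   0 for a single scan) and `per_scan` (numeric vector).
#' @export
fp_ratio <- function(conjugate) {
  fl <- conjugate$fluorophore
  per <- vapply(conjugate$scans, function(s) {
    amax <- conjugate_amax(s, fl)
    conc <- conjugate$protein_conc_M %||% protein_concentration(
      s, fl, conjugate$protein_eps280)
    if (conc <= 0) fq_validation_error("protein concentration must be > 0")
    amax / (fl$extinction_at_max * s$pathlength_cm * conc)
  }, 0)
  list(ratio = mean(per), rms = sqrt(mean((per - mean(per))^2)),
       per_scan = per)
}

#' Acceptor-to-donor fluorophore ratio
#'
#' Number of acceptor fluorophore molecules per donor fluorophore molecule
#' in the assay mixture, combining protein concentrations with the
#' conjugates' degrees of labeling:
#' `A/D = (acceptor_conc * F/P_acceptor) / (donor_conc * F/P_donor)`.
#'
#' @param donor_conc_nM,acceptor_conc_nM protein concentrations in nM.
#' @param fp_donor,fp_acceptor degree of labeling of each conjugate.
#' @return the dimensionless A/D ratio.
#' @export
ad_ratio <- function(donor_conc_nM, acceptor_conc_nM, fp_donor, fp_acceptor) {
  vals <- c(donor_conc_nM, acceptor_conc_nM, fp_donor, fp_acceptor)
  if (any(!is.finite(vals)) || any(vals <= 0))
    fq_validation_error("all A/D inputs must be positive")
  (acceptor_conc_nM * fp_acceptor) / (donor_conc_nM * fp_donor)
}
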