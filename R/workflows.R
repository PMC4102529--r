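# Plate-level orchestration: background correction, ratio-factor
# calibration from dedicated wells, Eq.-style signal decomposition, and
# the end-to-end dissociation-constant workflow.

# Blank handling and corrected-spectrum access for one plate. Blank wells
# are per-plate; multiple blanks are averaged.
prepare_plate <- function(scan, windows = analysis_windows()) {
  lay <- scan$layout
  blank_mean <- function(ex) {
    wells <- lay$well_id[lay$role == "blank"]
    specs <- Filter(Negate(is.null), lapply(wells, function(wl)
      scan$spectra[[spec_key(wl, ex)]]))
    if (length(specs) == 0L) return(NULL)
    if (length(specs) == 1L) specs[[1L]] else average_replicates(specs)$mean
  }
  blanks <- list()
  for (ex in c(windows$donor_ex_nm, windows$acceptor_ex_nm))
    blanks[[format(ex)]] <- blank_mean(ex)
  corrected <- function(well_id, ex) {
    s <- get_spectrum(scan, well_id, ex)
    b <- blanks[[format(ex)]]
    if (is.null(b)) s else subtract_background(s, b)
  }
  list(corrected = corrected, blanks = blanks)
}

# mean corrected spectrum over the replicate wells of one (role, conc)
condition_mean <- function(scan, prep, wells, ex) {
  specs <- lapply(wells, prep$corrected, ex = ex)
  if (length(specs) == 1L) specs[[1L]] else average_replicates(specs)$mean
}

#' Estimate the cross-talk ratio factors from a plate's calibration wells
#'
#' Donor-only wells (grouped by concentration, replicate-averaged) give
#' the bleed-through factor a; acceptor-only wells scanned under both
#' excitations give the direct-excitation factor b. Factors are computed
#' once per plate and applied plate-wide.
#'
#' @param scan a [plate_scan()] with `donor_only` and `acceptor_only`
#'   wells.
#' @param windows an [analysis_windows()].
#' @param prep internal; reuse an existing [prepare_plate()] result.
#' @return a [ratio_factors()].
#' @export
calibrate_factors <- function(scan, windows = analysis_windows(),
                              prep = NULL) {
  prep <- prep %||% prepare_plate(scan, windows)
  lay <- scan$layout

  don <- lay[lay$role == "donor_only", , drop = FALSE]
  if (nrow(don) == 0L)
    fq_config_error("plate has no donor_only calibration wells")
  don_groups <- split(don$well_id, don$donor_conc_nM)
  donor_means <- lapply(don_groups, condition_mean, scan = scan, prep = prep,
                        ex = windows$donor_ex_nm)
  ra <- ratio_factor_a(donor_means, windows)

  acc <- lay[lay$role == "acceptor_only", , drop = FALSE]
  if (nrow(acc) == 0L)
    fq_config_error("plate has no acceptor_only calibration wells")
  acc_groups <- split(acc$well_id, acc$acceptor_conc_nM)
  acc_exD <- lapply(acc_groups, condition_mean, scan = scan, prep = prep,
                    ex = windows$donor_ex_nm)
  acc_exA <- lapply(acc_groups, condition_mean, scan = scan, prep = prep,
                    ex = windows$acceptor_ex_nm)
  rb <- ratio_factor_b(acc_exD, acc_exA, windows)

  ratio_factors(ra$a, rb$b, a_rms = ra$rms, b_rms = rb$rms,
                n_a = ra$n, n_b = rb$n)
}

# replicate-averaged reference spectra (donor-only at donor_nM,
# acceptor-only at acceptor_nM under both excitations)
reference_spectra <- function(scan, windows, prep, donor_nM, acceptor_nM) {
  lay <- scan$layout
  dw <- lay$well_id[lay$role == "donor_only" & lay$donor_conc_nM == donor_nM]
  if (length(dw) == 0L)
    fq_config_error(sprintf("no donor_only reference wells at %g nM", donor_nM))
  aw <- lay$well_id[lay$role == "acceptor_only" &
                      lay$acceptor_conc_nM == acceptor_nM]
  if (length(aw) == 0L)
    fq_config_error(sprintf("no acceptor_only reference wells at %g nM",
                            acceptor_nM))
  list(donor = condition_mean(scan, prep, dw, windows$donor_ex_nm),
       acceptor_exD = condition_mean(scan, prep, aw, windows$donor_ex_nm),
       acceptor_exA = condition_mean(scan, prep, aw, windows$acceptor_ex_nm))
}

#' Decompose a titration plate into per-condition FRET signals
#'
#' For every mixture condition (grouped by acceptor concentration), the
#' replicate wells are blank-corrected and the three readings extracted:
#' `F_D` (donor peak, donor excitation), `F_DA` (acceptor peak, donor
#' excitation) and `F_A` (acceptor peak, acceptor excitation). The FRET
#' signal follows from [fret_signal()] with the plate's ratio factors,
#' per replicate; means and rms across the replicates are reported.
#'
#' @param scan a [plate_scan()] from the titration design.
#' @param windows an [analysis_windows()].
#' @param factors optional [ratio_factors()]; calibrated from the plate
#'   when `NULL`.
#' @return `data.frame` of class `fret_decomposition` with one row per
#'   acceptor concentration (columns `acceptor_nM`, `donor_nM`, `F_D`,
#'   `F_A`, `F_DA`, their rms, `F_FRET`, `F_FRET_rms`, `n_rep`), with
#'   attributes `factors` and `replicates` (list of per-condition
#'   replicate F_FRET vectors).
#' @export
decompose_titration <- function(scan, windows = analysis_windows(),
                                factors = NULL) {
  prep <- prepare_plate(scan, windows)
  if (is.null(factors)) factors <- calibrate_factors(scan, windows, prep)
  lay <- scan$layout
  mix <- lay[lay$role == "mixture", , drop = FALSE]
  if (nrow(mix) == 0L) fq_degenerate_error("plate has no mixture wells")
  concs <- sort(unique(mix$acceptor_conc_nM))

  rows <- list(); reps <- list()
  for (A in concs) {
    wells <- mix$well_id[mix$acceptor_conc_nM == A]
    per <- vapply(wells, function(wl) {
      m470 <- prep$corrected(wl, windows$donor_ex_nm)
      m53x <- prep$corrected(wl, windows$acceptor_ex_nm)
      fd <- peak_intensity(m470, windows$donor_peak_nm, windows$peak_halfwidth_nm)
      fda <- peak_intensity(m470, windows$acceptor_peak_nm, windows$peak_halfwidth_nm)
      fa <- peak_intensity(m53x, windows$acceptor_peak_nm, windows$peak_halfwidth_nm)
      c(F_D = fd, F_A = fa, F_DA = fda,
        F_FRET = fret_signal(fda, fd, fa, factors))
    }, c(F_D = 0, F_A = 0, F_DA = 0, F_FRET = 0))
    mu <- rowMeans(per)
    rms <- sqrt(rowMeans((per - mu)^2))
    rows[[length(rows) + 1L]] <- data.frame(
      acceptor_nM = A, donor_nM = mix$donor_conc_nM[mix$acceptor_conc_nM == A][1L],
      F_D = mu[["F_D"]], F_D_rms = rms[["F_D"]],
      F_A = mu[["F_A"]], F_A_rms = rms[["F_A"]],
      F_DA = mu[["F_DA"]], F_DA_rms = rms[["F_DA"]],
      F_FRET = mu[["F_FRET"]], F_FRET_rms = rms[["F_FRET"]],
      n_rep = length(wells))
    reps[[length(reps) + 1L]] <- per["F_FRET", ]
  }
  out <- do.call(rbind, rows)
  attr(out, "factors") <- factors
  attr(out, "replicates") <- reps
  class(out) <- c("fret_decomposition", "data.frame")
  out
}

#' Export a decomposition table
#'
#' One row per mixture condition with `F_D`, `F_A`, `F_DA`, the ratio
#' factors used, `F_FRET` and replicate rms values.
#'
#' @param decomp a [decompose_titration()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_decomposition <- function(decomp, path) {
  f <- attr(decomp, "factors")
  tab <- cbind(as.data.frame(decomp), a = f$a, b = f$b)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Dissociation-constant workflow on one plate
#'
#' Chains the full analysis: blank correction, ratio-factor calibration,
#' per-condition FRET-signal decomposition, and the ligand-depletion
#' binding fit for `Kd` and `F_FRETmax`.
#'
#' @param scan a [plate_scan()] (titration design) or a path to a
#'   plate-scan file.
#' @param windows an [analysis_windows()].
#' @param weights optional per-concentration fit weights (e.g. inverse
#'   replicate variance).
#' @return object of class `kd_result`: `fit` (a `binding_fit`),
#'   `decomposition`, `factors`, `series`.
#' @export
kd_workflow <- function(scan, windows = analysis_windows(), weights = NULL) {
  if (is.character(scan)) scan <- read_plate_scan(scan)
  decomp <- decompose_titration(scan, windows)
  series <- titration_series(decomp$acceptor_nM, decomp$F_FRET,
                             donor_nM = decomp$donor_nM[1L],
                             rms = decomp$F_FRET_rms,
                             replicates = attr(decomp, "replicates"))
  fit <- fit_binding(series, weights = weights)
  structure(list(fit = fit, decomposition = decomp,
                 factors = attr(decomp, "factors"), series = series),
            class = "kd_result")
}

#' @export
print.kd_result <- function(x, ...) {
  print(x$factors)
  print(x$fit)
  invisible(x)
}

#' Screening workflow on one plate
#'
#' Convenience wrapper: reads the plate if given a path, then runs
#' [analyze_screen()].
#'
#' @param scan a [plate_scan()] or file path.
#' @param config a [screen_config()].
#' @return a `screen_result`.
#' @export
screen_workflow <- function(scan, config = screen_config()) {
  if (is.character(scan)) scan <- read_plate_scan(scan)
  analyze_screen(scan, config = config)
}

#' Write a plain-text binding fit report
#'
#' @param fit a `binding_fit` (or `kd_result`).
#' @param path output path.
#' @param boot optional [bootstrap_ci()] result to include.
#' @return `path`, invisibly.
#' @export
export_fit_report <- function(fit, path, boot = NULL) {
  if (inherits(fit, "kd_result")) fit <- fit$fit
  lines <- c(
    "one-to-one ligand-depletion binding fit",
    sprintf("kd_nM\t%.6g", fit$kd_nM),
    sprintf("kd_se_nM\t%.6g", fit$kd_se_nM),
    sprintf("f_fret_max\t%.6g", fit$f_max),
    sprintf("f_fret_max_se\t%.6g", fit$f_max_se),
    sprintf("adj_r_squared\t%.6g", fit$adj_r_squared),
    sprintf("n_points\t%d", fit$n_points),
    sprintf("converged\t%s", fit$converged))
  if (!is.null(boot)) {
    lines <- c(lines,
               sprintf("kd_ci95\t%.6g\t%.6g", boot$kd_ci[1L], boot$kd_ci[2L]),
               sprintf("f_max_ci95\t%.6g\t%.6g",
                       boot$f_max_ci[1L], boot$f_max_ci[2L]))
  }
  lines <- c(lines, "", "acceptor_nM\tf_fret\tfitted\tresidual")
  s <- fit$series
  lines <- c(lines, sprintf("%g\t%.6g\t%.6g\t%.6g", s$acceptor_nM, s$f_fret,
                            fit$fitted, fit$residuals))
  writeLines(lines, path)
  invisible(path)
}
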