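# Competitive-inhibition screening analytics: per-dose inhibition
# efficiency, replicate statistics, ranking and significance annotation.

#' Inhibition efficiency from FRET efficiencies
#'
#' `100 * (F_control - F_x) / F_control`, the fractional reduction of the
#' control FRET efficiency caused by an inhibitor. Negative values
#' (apparent enhancers) are reported as-is.
#'
#' @param f_control_pct control (uninhibited) FRET efficiency in percent
#'   (> 0).
#' @param f_x_pct FRET efficiency with inhibitor, percent (vectorized).
#' @return inhibition efficiency in percent.
#' @export
inhibition_efficiency <- function(f_control_pct, f_x_pct) {
  if (!is.finite(f_control_pct) || f_control_pct <= 0)
    fq_degenerate_error("control FRET efficiency must be > 0")
  100 * (f_control_pct - f_x_pct) / f_control_pct
}

# first-order error propagation for the inhibition efficiency
inhibition_rms <- function(f_control, rms_control, f_x, rms_x) {
  ifelse(f_x == 0, 100 * rms_control / f_control,
         100 * abs(f_x / f_control) *
           sqrt((rms_control / f_control)^2 + (rms_x / f_x)^2))
}

sig_stars <- function(p) {
  ifelse(p < 0.005, "**", ifelse(p < 0.05, "*", "NS"))
}

#' Compare two inhibitor conditions by t-test
#'
#' Two-sided two-sample Student's t-test (equal variances by default, as
#' is conventional for triplicate plate data; set `var_equal = FALSE`
#' for Welch's test) on replicate-level FRET or inhibition efficiencies.
#' Significance coding: `**` for p < 0.005, `*` for p < 0.05, `NS`
#' otherwise.
#'
#' @param rep_a,rep_b numeric vectors of replicate-level efficiencies
#'   (>= 2 each).
#' @param var_equal use the pooled-variance Student test (default).
#' @return list with `p_value`, `stars`, `mean_a`, `mean_b`.
#' @export
compare_inhibitors <- function(rep_a, rep_b, var_equal = TRUE) {
  if (length(rep_a) < 2L || length(rep_b) < 2L)
    fq_validation_error("need at least two replicates per group")
  const_a <- stats::sd(rep_a) == 0; const_b <- stats::sd(rep_b) == 0
  if (const_a && const_b) {
    # degenerate separation limits: identical -> p = 1; distinct -> p -> 0
    p <- if (isTRUE(all.equal(mean(rep_a), mean(rep_b)))) 1 else 0
  } else {
    p <- stats::t.test(rep_a, rep_b, var.equal = var_equal)$p.value
  }
  list(p_value = p, stars = sig_stars(p), mean_a = mean(rep_a),
       mean_b = mean(rep_b))
}

#' Screening configuration
#'
#' @param fluors named list with `donor` and `acceptor`
#'   [fluorophore_params()] (defaults to the shipped constants).
#' @param fp_donor,fp_acceptor degrees of labeling used to convert
#'   protein to fluorophore concentrations when computing absorbances.
#' @param windows an [analysis_windows()].
#' @param var_equal equal-variance t-test (see [compare_inhibitors()]).
#' @param p_adjust multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` by default (per-dose tests are
#'   reported raw), `"holm"` available.
#' @return list of class `screen_config`.
#' @export
screen_config <- function(fluors = read_fluorophore_params(),
                          fp_donor = 1.48, fp_acceptor = 3.14,
                          windows = analysis_windows(), var_equal = TRUE,
                          p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (is.null(fluors$donor))
    fluors <- list(donor = fluors[[1L]], acceptor = fluors[[2L]])
  structure(list(fluors = fluors, fp_donor = fp_donor,
                 fp_acceptor = fp_acceptor, windows = windows,
                 var_equal = var_equal, p_adjust = p_adjust),
            class = "screen_config")
}

# donor and acceptor absorbances at the donor excitation wavelength, for
# the efficiency estimator. The acceptor's weak absorbance there is
# inferred from the measured cross-talk factor b (b times its absorbance
# at its own excitation wavelength), which keeps the estimator consistent
# with the direct-excitation reference scan.
assay_absorbances <- function(config, donor_nM, acceptor_nM, b) {
  w <- config$windows
  fd <- config$fluors$donor; fa <- config$fluors$acceptor
  A_D <- fd$extinction_at_max * fluor_rel_absorbance(fd, w$donor_ex_nm) *
    config$fp_donor * donor_nM * 1e-9
  A_A <- b * fa$extinction_at_max *
    fluor_rel_absorbance(fa, w$acceptor_ex_nm) *
    config$fp_acceptor * acceptor_nM * 1e-9
  c(A_D = A_D, A_A = A_A)
}

#' Analyze an inhibitor-screening plate
#'
#' Full screening analytics on one plate: blank correction, ratio-factor
#' calibration from the dedicated donor-only/acceptor-only wells,
#' replicate-level cross-talk-corrected FRET efficiency per condition
#' ([fret_efficiency()]), inhibition efficiency against the uninhibited
#' control, first-order error propagation, per-dose ranking and t-test
#' annotation against the control.
#'
#' @param scan a [plate_scan()] containing control mixture wells, at
#'   least one inhibitor condition, calibration wells and blanks.
#' @param factors optional [ratio_factors()]; estimated from the plate's
#'   calibration wells when `NULL`.
#' @param config a [screen_config()].
#' @return object of class `screen_result`: `control` (efficiency mean,
#'   rms, replicate values), `records` (one row per inhibitor dose with
#'   efficiency, inhibition, propagated rms, p-value, stars and per-dose
#'   rank), `factors`, `replicates` (per-condition efficiency vectors).
#' @export
analyze_screen <- function(scan, factors = NULL, config = screen_config()) {
  w <- config$windows
  prep <- prepare_plate(scan, w)
  if (is.null(factors)) factors <- calibrate_factors(scan, w, prep)

  lay <- scan$layout
  ctrl_wells <- lay$well_id[lay$role == "mixture"]
  if (length(ctrl_wells) == 0L)
    fq_config_error("plate has no control mixture wells")
  inh_lay <- lay[lay$role == "mixture_inhibitor", , drop = FALSE]
  if (nrow(inh_lay) == 0L)
    fq_config_error("plate has no inhibitor conditions")

  D <- lay$donor_conc_nM[lay$role == "mixture"][1L]
  A <- lay$acceptor_conc_nM[lay$role == "mixture"][1L]
  refs <- reference_spectra(scan, w, prep, donor_nM = D, acceptor_nM = A)
  ab <- assay_absorbances(config, D, A, factors$b)

  cond_eff <- function(wells) {
    vapply(wells, function(wl) {
      mix <- prep$corrected(wl, w$donor_ex_nm)
      fret_efficiency(mix, refs$donor, refs$acceptor_exD, refs$acceptor_exA,
                      A_D = ab[["A_D"]], A_A = ab[["A_A"]],
                      windows = w)$E_pct
    }, 0)
  }

  ctrl_reps <- cond_eff(ctrl_wells)
  fc <- mean(ctrl_reps)
  fc_rms <- sqrt(mean((ctrl_reps - fc)^2))
  if (fc <= 0)
    fq_degenerate_error("control FRET efficiency is not positive")

  key <- paste(inh_lay$inhibitor_id, inh_lay$inhibitor_conc_uM)
  groups <- split(inh_lay$well_id, key)
  meta <- unique(data.frame(inhibitor_id = inh_lay$inhibitor_id,
                            dose_uM = inh_lay$inhibitor_conc_uM,
                            key = key, stringsAsFactors = FALSE))
  reps <- lapply(meta$key, function(k) cond_eff(groups[[k]]))
  names(reps) <- meta$key

  fx <- vapply(reps, mean, 0)
  fx_rms <- vapply(reps, function(r) sqrt(mean((r - mean(r))^2)), 0)
  # per-replicate inhibition, then averaged; identical in mean to the
  # mean-based value, but the replicate spread is also retained
  inh_reps <- lapply(reps, function(r) inhibition_efficiency(fc, r))
  inh_mean <- vapply(inh_reps, mean, 0)
  inh_rep_rms <- vapply(inh_reps, function(r) sqrt(mean((r - mean(r))^2)), 0)
  inh_prop_rms <- inhibition_rms(fc, fc_rms, fx, fx_rms)
  pvals <- vapply(seq_along(reps), function(i)
    compare_inhibitors(reps[[i]], ctrl_reps, var_equal = config$var_equal)$p_value, 0)
  if (config$p_adjust != "none") pvals <- stats::p.adjust(pvals, config$p_adjust)

  records <- data.frame(
    inhibitor_id = meta$inhibitor_id, dose_uM = meta$dose_uM,
    fret_efficiency_pct = fx, fret_efficiency_rms = fx_rms,
    inhibition_pct = inh_mean, inhibition_rms = inh_prop_rms,
    inhibition_replicate_rms = inh_rep_rms,
    enhancer = inh_mean < 0,
    p_vs_control = pvals, stars = sig_stars(pvals),
    row.names = NULL, stringsAsFactors = FALSE)
  records <- records[order(records$dose_uM, -records$inhibition_pct), ]
  records$rank_at_dose <- stats::ave(-records$inhibition_pct, records$dose_uM,
                                     FUN = rank)
  structure(list(control = list(efficiency_pct = fc, rms = fc_rms,
                                replicates = ctrl_reps),
                 records = records, factors = factors, replicates = reps,
                 donor_nM = D, acceptor_nM = A),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("FRET inhibitor screen: control efficiency %.2f%% +/- %.2f (n = %d)\n",
              x$control$efficiency_pct, x$control$rms,
              length(x$control$replicates)))
  df <- x$records
  df$fret_efficiency_pct <- sprintf("%.2f", df$fret_efficiency_pct)
  df$inhibition_pct <- sprintf("%.2f", clip_pct(df$inhibition_pct))
  print(df[, c("inhibitor_id", "dose_uM", "fret_efficiency_pct",
               "inhibition_pct", "stars", "rank_at_dose")],
        row.names = FALSE)
  invisible(x)
}

#' Export a screen result as a delimited table
#'
#' One row per inhibitor condition with efficiencies, inhibition,
#' propagated rms, p-value and stars.
#'
#' @param result a `screen_result` from [analyze_screen()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
export_screen <- function(result, path) {
  utils::write.table(result$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
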