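# One-to-one mass-action binding with ligand depletion, and the
# nonlinear titration fit for (Kd, F_FRETmax).

#' Equilibrium complex concentration under ligand depletion
#'
#' Physically admissible root of the mass-action quadratic
#' `[DA]^2 - (A + D + Kd)[DA] + A*D = 0` for a one-to-one complex with
#' total concentrations `A` and `D`:
#' `[DA] = ((A + D + Kd) - sqrt((A + D + Kd)^2 - 4*A*D)) / 2`,
#' evaluated in the numerically stable form `2AD / (s + sqrt(s^2 - 4AD))`
#' so that small complexes at weak binding do not suffer cancellation.
#' The result always satisfies `0 <= [DA] <= min(A, D)` and is symmetric
#' in `A` and `D`.
#'
#' @param A_total,D_total total concentrations in nM (vectorized over
#'   `A_total`).
#' @param kd dissociation constant in nM (> 0).
#' @return complex concentration in nM.
#' @export
bound_complex <- function(A_total, D_total, kd) {
  if (any(A_total < 0) || any(D_total < 0))
    fq_validation_error("concentrations must be >= 0")
  if (any(kd <= 0)) fq_validation_error("kd must be > 0")
  s <- A_total + D_total + kd
  disc <- s^2 - 4 * A_total * D_total
  disc[disc < 0] <- 0  # guard roundoff
  2 * A_total * D_total / (s + sqrt(disc))
}

#' Predicted FRET signal for a titration point
#'
#' Saturation model tying the measured FRET emission to the bound
#' complex fraction: `F = F_max * [DA] / D`. Monotone non-decreasing in
#' `A`, zero at `A = 0`, and approaching `F_max` as `A` grows large.
#'
#' @param A acceptor total concentration in nM (vectorized).
#' @param D donor total concentration in nM (> 0).
#' @param kd dissociation constant in nM.
#' @param f_max saturation FRET amplitude in RFU.
#' @return predicted FRET signal in RFU.
#' @export
predicted_fret <- function(A, D, kd, f_max) {
  if (any(D <= 0)) fq_validation_error("D must be > 0")
  f_max * bound_complex(A, D, kd) / D
}

#' Assemble a titration series
#'
#' @param acceptor_nM strictly increasing, non-negative acceptor total
#'   concentrations.
#' @param f_fret extracted FRET signal per concentration (RFU), one entry
#'   per concentration (typically the mean over replicates).
#' @param donor_nM fixed donor total concentration in nM.
#' @param rms optional per-concentration replicate rms of `f_fret`.
#' @param replicates optional list (one element per concentration) of
#'   replicate-level FRET signals, used by [bootstrap_ci()].
#' @return a `data.frame` of class `titration_series` with attributes
#'   `donor_nM` and `replicates`.
#' @export
titration_series <- function(acceptor_nM, f_fret, donor_nM, rms = NULL,
                             replicates = NULL) {
  if (any(acceptor_nM < 0)) fq_validation_error("acceptor concentrations must be >= 0")
  if (any(diff(acceptor_nM) <= 0))
    fq_validation_error("acceptor concentrations must be strictly increasing")
  if (length(f_fret) != length(acceptor_nM))
    fq_validation_error("one f_fret entry per acceptor concentration required")
  if (donor_nM <= 0) fq_validation_error("donor_nM must be > 0")
  if (!is.null(replicates) && length(replicates) != length(acceptor_nM))
    fq_validation_error("replicates must have one element per concentration")
  out <- data.frame(acceptor_nM = acceptor_nM, f_fret = f_fret,
                    rms = rms %||% NA_real_)
  attr(out, "donor_nM") <- donor_nM
  attr(out, "replicates") <- replicates
  class(out) <- c("titration_series", "data.frame")
  out
}

# half-max interpolation for the Kd start value
kd_start_heuristic <- function(A, y) {
  ymax <- max(y)
  if (ymax <= 0) return(NA_real_)
  half <- ymax / 2
  above <- which(y >= half)
  i <- above[1L]
  if (i == 1L) return(max(A[1L], 1))
  x0 <- A[i - 1L]; x1 <- A[i]; y0 <- y[i - 1L]; y1 <- y[i]
  if (y1 == y0) return(x1)
  x0 + (half - y0) * (x1 - x0) / (y1 - y0)
}

#' Fit the ligand-depletion binding isotherm to a titration
#'
#' Least-squares estimation of `(Kd, F_max)` in
#' `F = F_max * [DA](A, D, Kd) / D` by bounded Levenberg-Marquardt, with
#' multi-start initialization: `F_max` starts at the largest observation,
#' `Kd` at the half-maximum concentration (linear interpolation) and at a
#' 5-point log-spaced spread a decade either side of it, because the
#' model's flat saturation tail can trap single-start optimizers.
#' Standard errors come from the Jacobian at the optimum; the adjusted
#' R-squared uses the fitted concentration points (`n` points, `p = 2`).
#'
#' @param series a [titration_series()].
#' @param weights optional per-point weights (e.g. inverse variance);
#'   unweighted by default.
#' @return object of class `binding_fit` with elements `kd_nM`,
#'   `kd_se_nM`, `f_max`, `f_max_se`, `adj_r_squared`, `r_squared`,
#'   `residuals`, `fitted`, `converged`, `at_bounds`, `n_points`,
#'   `series`.
#' @export
fit_binding <- function(series, weights = NULL) {
  A <- series$acceptor_nM; y <- series$f_fret
  D <- attr(series, "donor_nM")
  if (length(unique(A)) < 4L)
    fq_validation_error("need at least 4 distinct acceptor concentrations")
  if (all(y == 0))
    fq_degenerate_error("all FRET signals are zero; nothing to fit")
  w <- weights %||% rep(1, length(y))

  fmax0 <- max(y)
  kd0 <- kd_start_heuristic(A, y)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(A[A > 0])
  starts <- unique(pmin(pmax(kd0 * 10^seq(-1, 1, length.out = 5), 1e-3), 1e6))
  lower <- c(kd = 1e-3, f_max = 1e-12)
  upper <- c(kd = 1e6, f_max = 100 * fmax0)

  best <- NULL; best_dev <- Inf
  for (k0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ predicted_fret(A, D, kd, f_max),
        start = list(kd = k0, f_max = fmax0),
        lower = lower, upper = upper, weights = w,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      dev <- stats::deviance(fit)
      if (dev < best_dev) { best <- fit; best_dev <- dev }
    }
  }
  if (is.null(best))
    fq_fit_error("binding fit failed to converge from all starts",
                 best = list(kd = kd0, f_max = fmax0))

  est <- stats::coef(best)
  se <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                 error = function(e) c(kd = NA_real_, f_max = NA_real_))
  at_bounds <- c(kd = est[["kd"]] <= lower[["kd"]] * (1 + 1e-8) ||
                      est[["kd"]] >= upper[["kd"]] * (1 - 1e-8),
                 f_max = est[["f_max"]] >= upper[["f_max"]] * (1 - 1e-8))
  if (any(at_bounds)) se[] <- Inf

  fitted <- predicted_fret(A, D, est[["kd"]], est[["f_max"]])
  res <- y - fitted
  n <- length(y); p <- 2L
  ss_res <- sum(res^2); ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_
  adj <- if (!is.na(r2) && n > p + 1L) 1 - (1 - r2) * (n - 1) / (n - p - 1)
         else NA_real_

  structure(list(kd_nM = est[["kd"]], kd_se_nM = se[["kd"]],
                 f_max = est[["f_max"]], f_max_se = se[["f_max"]],
                 r_squared = r2, adj_r_squared = adj, residuals = res,
                 fitted = fitted, converged = isTRUE(best$convInfo$isConv),
                 at_bounds = at_bounds, n_points = n, series = series),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("One-to-one ligand-depletion binding fit\n")
  cat(sprintf("  Kd      = %.4g +/- %.3g nM\n", x$kd_nM, x$kd_se_nM))
  cat(sprintf("  F_max   = %.4g +/- %.3g RFU\n", x$f_max, x$f_max_se))
  cat(sprintf("  adj R^2 = %.4f  (n = %d points)\n", x$adj_r_squared, x$n_points))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  if (any(x$at_bounds)) cat("  WARNING: parameter at bounds; standard errors unbounded\n")
  invisible(x)
}

#' Plot a binding fit
#'
#' Data points with the fitted saturation curve, on a linear
#' concentration axis.
#'
#' @param x a `binding_fit`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.binding_fit <- function(x, ...) {
  s <- x$series
  D <- attr(s, "donor_nM")
  graphics::plot(s$acceptor_nM, s$f_fret, pch = 19,
                 xlab = "acceptor total (nM)", ylab = "F_FRET (RFU)", ...)
  if (!all(is.na(s$rms)))
    graphics::arrows(s$acceptor_nM, s$f_fret - s$rms, s$acceptor_nM,
                     s$f_fret + s$rms, angle = 90, code = 3, length = 0.02)
  grid_a <- seq(min(s$acceptor_nM), max(s$acceptor_nM), length.out = 200)
  graphics::lines(grid_a, predicted_fret(grid_a, D, x$kd_nM, x$f_max),
                  col = "firebrick", lwd = 2)
  invisible(x)
}

#' Bootstrap confidence intervals for the binding parameters
#'
#' Case-resampling bootstrap. When the series carries replicate-level
#' FRET signals, each draw resamples replicates within every
#' concentration and refits on the resampled means; otherwise the
#' concentration points themselves are resampled. Reproducible under a
#' fixed seed.
#'
#' @param series a [titration_series()].
#' @param n_boot number of bootstrap draws (>= 100).
#' @param seed integer seed.
#' @param level interval level (default 0.95).
#' @return list with `kd_ci`, `f_max_ci` (percentile intervals),
#'   `kd_boot`, `f_max_boot` (the draws), `n_boot`, `n_failed`.
#' @export
bootstrap_ci <- function(series, n_boot = 500, seed = 1, level = 0.95) {
  if (n_boot < 100) fq_validation_error("n_boot must be >= 100")
  base_fit <- fit_binding(series)  # pre: must converge on the full series
  reps <- attr(series, "replicates")
  D <- attr(series, "donor_nM")
  alpha <- (1 - level) / 2

  draws <- with_seed(seed, {
    kd <- numeric(0); fm <- numeric(0); failed <- 0L
    for (i in seq_len(n_boot)) {
      if (!is.null(reps)) {
        y <- vapply(reps, function(r) mean(sample(r, length(r), replace = TRUE)), 0)
        s <- titration_series(series$acceptor_nM, y, D)
      } else {
        idx <- sort(sample(seq_len(nrow(series)), nrow(series), replace = TRUE))
        idx <- idx[!duplicated(series$acceptor_nM[idx])]
        if (length(idx) < 4L) { failed <- failed + 1L; next }
        s <- titration_series(series$acceptor_nM[idx], series$f_fret[idx], D)
      }
      f <- tryCatch(fit_binding(s), error = function(e) NULL)
      if (is.null(f)) { failed <- failed + 1L; next }
      kd <- c(kd, f$kd_nM); fm <- c(fm, f$f_max)
    }
    list(kd = kd, fm = fm, failed = failed)
  })

  list(kd_ci = stats::quantile(draws$kd, c(alpha, 1 - alpha), names = FALSE),
       f_max_ci = stats::quantile(draws$fm, c(alpha, 1 - alpha), names = FALSE),
       kd_boot = draws$kd, f_max_boot = draws$fm,
       kd_hat = base_fit$kd_nM, f_max_hat = base_fit$f_max,
       n_boot = n_boot, n_failed = draws$failed)
}
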