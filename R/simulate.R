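# Physically structured synthetic plate scans: emission bands, binding
# equilibria, competitive inhibition, cross-talk and replicate noise.
# The generator is first-class, tested code; its noiseless output is the
# package's parameter-recovery surface.

#' Specify a simulated FRET experiment
#'
#' The defaults reproduce the assay design this package targets: donor
#' conjugate fixed at 100 nM, acceptor titrated from 0 to 1.6 µM over 12
#' concentrations, cross-talk ratio factors a = 0.129 and b = 0.101,
#' degrees of labeling 1.48 (donor) and 3.14 (acceptor), a dissociation
#' constant of 17.93 nM with saturation FRET amplitude 6.33e3 RFU,
#' replicate structure 3 samples x 3 reads, and 2% multiplicative noise.
#'
#' @param kd_nM dissociation constant of the donor-acceptor complex.
#' @param f_fret_max_RFU saturation FRET amplitude for the titration
#'   scenario.
#' @param donor_total_nM fixed donor (protein) concentration.
#' @param acceptor_totals_nM acceptor titration series in nM.
#' @param crosstalk_a,crosstalk_b target ratio factors injected into the
#'   donor and acceptor bands.
#' @param fp_donor,fp_acceptor degrees of labeling of the two conjugates.
#' @param control_efficiency_pct apparent FRET efficiency (%) of the
#'   uninhibited screen mixture; fixes the per-complex transfer
#'   efficiency of the screen scenario.
#' @param screen_donor_nM,screen_acceptor_nM screen mixture composition.
#' @param inhibitors list of `list(id, ki_uM, doses_uM)` competitive
#'   inhibitors for [simulate_screen()].
#' @param noise_cv multiplicative (log-normal) noise coefficient of
#'   variation per read; 0 gives noiseless data.
#' @param background_RFU additive background level (removed by the blank
#'   wells during analysis).
#' @param n_samples,n_reads replicate structure; each condition is
#'   emitted as `n_samples * n_reads` replicate wells.
#' @param seed integer seed; mandatory, stored in the ground-truth
#'   ledger. There is no hidden global randomness.
#' @param grid_nm emission wavelength grid.
#' @param donor_cal_nM,acceptor_cal_nM calibration-well concentration
#'   series for the ratio factors.
#' @param windows an [analysis_windows()]; also defines the measurement
#'   convention the generator calibrates against.
#' @param fluors named list with `donor` and `acceptor`
#'   [fluorophore_params()]; defaults to the shipped dye constants.
#' @param gain instrument gain; every emitted intensity is linear in it
#'   (reference value 100). The extracted `a`, `b`, `Kd`, efficiencies
#'   and F/P ratios are gain-invariant; amplitudes (F_FRETmax) scale
#'   with it.
#' @param rfu_per_absorbance instrument photon-budget scale at the
#'   reference gain: RFU emitted at a peak per unit
#'   (absorbance x quantum yield). The default makes the titration's
#'   saturation amplitude correspond to a per-complex transfer
#'   efficiency of about 0.9, as expected for an optimized FRET pair
#'   carrying multiple acceptors per donor; lower scales inflate the
#'   direct-acceptor background relative to the sensitized signal and
#'   degrade the extraction's error budget.
#' @param donor_band,donor_tail_band,acceptor_band [band_shape()]s for
#'   the emission profiles (amplitudes are derived from the photon
#'   budget, not from the shapes).
#' @return list of class `simulation_spec`.
#' @export
simulation_spec <- function(
    kd_nM = 17.93, f_fret_max_RFU = 6330, donor_total_nM = 100,
    acceptor_totals_nM = c(0, 10, 25, 50, 75, 100, 150, 250, 400, 700, 1100, 1600),
    crosstalk_a = 0.129, crosstalk_b = 0.101,
    fp_donor = 1.48, fp_acceptor = 3.14,
    control_efficiency_pct = 53.51,
    screen_donor_nM = 100, screen_acceptor_nM = 100,
    inhibitors = default_inhibitors(),
    noise_cv = 0.02, background_RFU = 50,
    n_samples = 3, n_reads = 3, seed = 1,
    grid_nm = seq(410, 700, by = 1),
    donor_cal_nM = c(100, 200, 300),
    acceptor_cal_nM = c(100, 200, 300, 400, 500),
    windows = analysis_windows(),
    fluors = read_fluorophore_params(),
    gain = 100,
    rfu_per_absorbance = 9.7e6,
    donor_band = band_shape(520, 35, 0.15),
    donor_tail_band = band_shape(570, 60, 0.25),
    acceptor_band = band_shape(570, 32, 0.5)) {
  if (is.null(seed) || !is.finite(seed))
    fq_validation_error("a simulation seed is mandatory")
  pos <- c(kd_nM, f_fret_max_RFU, donor_total_nM, fp_donor, fp_acceptor,
           rfu_per_absorbance, gain, n_samples, n_reads)
  if (any(pos <= 0)) fq_validation_error("physical parameters must be positive")
  if (noise_cv < 0 || background_RFU < 0)
    fq_validation_error("noise_cv and background_RFU must be >= 0")
  if (crosstalk_a < 0 || crosstalk_a >= 1 || crosstalk_b < 0 || crosstalk_b >= 1)
    fq_validation_error("crosstalk factors must lie in [0, 1)")
  fl <- fluors
  if (is.null(fl$donor)) {
    # shipped config names the dyes; map them onto roles
    fl <- list(donor = fluors[[1L]], acceptor = fluors[[2L]])
  }
  out <- mget(names(formals(simulation_spec)))
  out$fluors <- fl
  structure(out, class = "simulation_spec")
}

#' Default competitive-inhibitor panel for the screen generator
#'
#' A lovastatin-like potent small molecule (doses 0.2-200 µM) and three
#' peptide competitors of decreasing potency (doses 0.02-20 µM),
#' mirroring the assay's positive control and peptide panel.
#'
#' @return list of `list(id, ki_uM, doses_uM)`.
#' @export
default_inhibitors <- function() {
  list(
    list(id = "lovastatin",   ki_uM = 0.00742, doses_uM = c(0.2, 2, 20, 200)),
    list(id = "CD11a_237-261", ki_uM = 0.5,    doses_uM = c(0.02, 0.2, 2, 20)),
    list(id = "CD11a_441-465", ki_uM = 2,      doses_uM = c(0.02, 0.2, 2, 20)),
    list(id = "CD11a_456-465", ki_uM = 10,     doses_uM = c(0.02, 0.2, 2, 20)))
}

# ---- internal photon-budget context ---------------------------------------

# window-mean of a raw shape vector under the measurement convention
shape_window_mean <- function(values, grid, center, halfwidth) {
  s <- emission_spectrum("cal", 470, grid, values)
  peak_intensity(s, center, halfwidth)
}

# Everything derived once per simulation: normalized band shapes
# (calibrated so their measured window-mean peak is exactly 1), the donor
# red-tail weight that realizes the target a-factor under the measurement
# convention, and the per-nM signal scales from the photon budget.
sim_context <- function(spec) {
  w <- spec$windows
  grid <- spec$grid_nm
  hw <- w$peak_halfwidth_nm

  g <- band_values(spec$donor_band, grid)       # donor main band
  h <- band_values(spec$donor_tail_band, grid)  # donor red tail
  aa <- band_values(spec$acceptor_band, grid)   # acceptor band

  g520 <- shape_window_mean(g, grid, w$donor_peak_nm, hw)
  g570 <- shape_window_mean(g, grid, w$acceptor_peak_nm, hw)
  h520 <- shape_window_mean(h, grid, w$donor_peak_nm, hw)
  h570 <- shape_window_mean(h, grid, w$acceptor_peak_nm, hw)
  a_t <- spec$crosstalk_a
  c_tail <- (a_t * g520 - g570) / (h570 - a_t * h520)
  if (!is.finite(c_tail) || c_tail < 0)
    fq_validation_error("donor band shapes cannot realize the requested crosstalk_a")
  dshape <- g + c_tail * h
  dshape <- dshape / shape_window_mean(dshape, grid, w$donor_peak_nm, hw)
  ashape <- aa / shape_window_mean(aa, grid, w$acceptor_peak_nm, hw)

  fl_d <- spec$fluors$donor; fl_a <- spec$fluors$acceptor
  # absorbance per nM of dye-equivalent protein (1 cm path), at the two
  # excitation wavelengths; the F/P ratio converts protein to dye moles
  abs_d_ex <- fl_d$extinction_at_max *
    fluor_rel_absorbance(fl_d, w$donor_ex_nm) * 1e-9 * spec$fp_donor
  abs_a_exA <- fl_a$extinction_at_max *
    fluor_rel_absorbance(fl_a, w$acceptor_ex_nm) * 1e-9 * spec$fp_acceptor
  G <- spec$rfu_per_absorbance
  M_D <- G * abs_d_ex * fl_d$quantum_yield    # donor peak RFU per nM
  M_A <- G * abs_a_exA * fl_a$quantum_yield   # acceptor peak RFU per nM (own ex)
  sens_per_nM <- G * abs_d_ex * fl_a$quantum_yield  # sensitized RFU per nM donor at E=1

  list(grid = grid, windows = w, dshape = dshape, ashape = ashape,
       c_tail = c_tail, M_D = M_D, M_A = M_A, sens_per_nM = sens_per_nM,
       abs_d_ex_per_nM = abs_d_ex, abs_a_exA_per_nM = abs_a_exA,
       gf = spec$gain / 100)
}

# log-normal multiplicative noise with mean 1 and sd = cv, plus background
emit_noisy <- function(values, spec) {
  v <- values + spec$background_RFU
  if (spec$noise_cv > 0) {
    sdl <- sqrt(log(1 + spec$noise_cv^2))
    v <- v * stats::rlnorm(length(v), meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  v
}

sim_meta <- function(spec) {
  list(instrument = "synthetic", gain = spec$gain, ex_bandwidth_nm = 9,
       em_bandwidth_nm = 20, integration_time_us = 20)
}

# Emit n_samples*n_reads replicate wells for one condition, at one or two
# excitations. `signals` is a named list ex_nm -> noiseless intensity vector.
emit_condition <- function(state, signals, role_row) {
  spec <- state$spec
  n_rep <- spec$n_samples * spec$n_reads
  for (r in seq_len(n_rep)) {
    state$well_n <- state$well_n + 1L
    wid <- sprintf("W%03d", state$well_n)
    lay <- cbind(data.frame(well_id = wid, stringsAsFactors = FALSE), role_row)
    state$layout[[length(state$layout) + 1L]] <- lay
    for (ex in names(signals)) {
      s <- emission_spectrum(wid, as.numeric(ex), spec$grid_nm,
                             emit_noisy(signals[[ex]], spec),
                             gain = spec$gain, ex_bandwidth_nm = 9,
                             em_bandwidth_nm = 20, integration_time_us = 20)
      state$spectra[[length(state$spectra) + 1L]] <- s
    }
    state$truth[[length(state$truth) + 1L]] <-
      cbind(data.frame(well_id = wid, stringsAsFactors = FALSE),
            state$truth_row)
  }
  state
}

new_sim_state <- function(spec) {
  e <- new.env(parent = emptyenv())
  e$spec <- spec; e$well_n <- 0L
  e$spectra <- list(); e$layout <- list(); e$truth <- list()
  e
}

finish_sim <- function(state, ctx, extra) {
  scan <- plate_scan(state$spectra,
                     do.call(rbind, state$layout), sim_meta(state$spec))
  ledger <- c(list(seed = state$spec$seed,
                   noise_cv = state$spec$noise_cv,
                   crosstalk_a = state$spec$crosstalk_a,
                   crosstalk_b = state$spec$crosstalk_b,
                   donor_tail_weight = ctx$c_tail,
                   donor_peak_rfu_per_nM = ctx$M_D,
                   acceptor_peak_rfu_per_nM = ctx$M_A,
                   wells = do.call(rbind, state$truth)),
              extra)
  list(scan = scan, ledger = ledger)
}

# mixture signal vectors for given composition and apparent efficiency
mixture_signals <- function(ctx, spec, D, A, E_app, f_sens) {
  mix470 <- ctx$gf * ((1 - E_app) * ctx$M_D * D * ctx$dshape +
    spec$crosstalk_b * ctx$M_A * A * ctx$ashape +
    f_sens * ctx$ashape)
  mix530 <- ctx$gf * ctx$M_A * A * ctx$ashape
  out <- list(mix470, mix530)
  names(out) <- c(as.character(spec$windows$donor_ex_nm),
                  as.character(spec$windows$acceptor_ex_nm))
  out
}

calibration_conditions <- function(state, ctx, spec) {
  exD <- as.character(spec$windows$donor_ex_nm)
  exA <- as.character(spec$windows$acceptor_ex_nm)
  # blanks (both excitations)
  blank_sig <- stats::setNames(
    list(numeric(length(ctx$grid)), numeric(length(ctx$grid))), c(exD, exA))
  state$truth_row <- data.frame(condition = "blank", f_bound = NA_real_,
                                E_app = NA_real_, f_fret_true = NA_real_)
  state <- emit_condition(state, blank_sig, well_role("blank"))
  # donor-only calibration series (donor excitation only)
  for (conc in spec$donor_cal_nM) {
    sig <- stats::setNames(list(ctx$gf * ctx$M_D * conc * ctx$dshape), exD)
    state$truth_row <- data.frame(condition = sprintf("donor_cal_%g", conc),
                                  f_bound = NA_real_, E_app = NA_real_,
                                  f_fret_true = NA_real_)
    state <- emit_condition(state, sig, well_role("donor_only",
                                                  donor_conc_nM = conc))
  }
  # acceptor-only calibration series (both excitations)
  for (conc in spec$acceptor_cal_nM) {
    direct <- ctx$gf * ctx$M_A * conc * ctx$ashape
    sig <- stats::setNames(list(spec$crosstalk_b * direct, direct), c(exD, exA))
    state$truth_row <- data.frame(condition = sprintf("acceptor_cal_%g", conc),
                                  f_bound = NA_real_, E_app = NA_real_,
                                  f_fret_true = NA_real_)
    state <- emit_condition(state, sig, well_role("acceptor_only",
                                                  acceptor_conc_nM = conc))
  }
  state
}

#' Simulate the binding-titration plate
#'
#' Generates a full plate for the dissociation-constant workflow: blank
#' wells, donor-only and acceptor-only calibration series, and the
#' titration mixtures (fixed donor, varied acceptor, both excitations).
#' For each acceptor concentration the bound complex follows
#' [bound_complex()]; the donor band is quenched by the apparent transfer
#' efficiency, the sensitized acceptor emission carries
#' `f_fret_max * bound / D` at the acceptor peak, and donor bleed-through
#' and acceptor direct excitation reproduce the configured cross-talk
#' factors. Every latent quantity is recorded in the ground-truth ledger.
#'
#' @param spec a [simulation_spec()].
#' @return list with `scan` (a [plate_scan()]) and `ledger` (ground
#'   truth: per-well bound fractions, apparent efficiencies, true FRET
#'   signals, derived photon-budget constants and the seed).
#' @export
simulate_titration <- function(spec = simulation_spec()) {
  ctx <- sim_context(spec)
  D <- spec$donor_total_nM
  # per-complex transfer efficiency implied by the requested F_FRETmax
  e_tr <- spec$f_fret_max_RFU / (ctx$sens_per_nM * D)
  if (e_tr > 1)
    fq_validation_error(sprintf(
      "f_fret_max_RFU implies per-complex transfer efficiency %.3f > 1; increase rfu_per_absorbance", e_tr))
  with_seed(spec$seed, {
    state <- new_sim_state(spec)
    state <- calibration_conditions(state, ctx, spec)
    for (A in spec$acceptor_totals_nM) {
      fb <- bound_complex(A, D, spec$kd_nM) / D
      f_true <- spec$f_fret_max_RFU * fb
      e_app <- e_tr * fb
      state$truth_row <- data.frame(condition = sprintf("titration_%g", A),
                                    f_bound = fb, E_app = e_app,
                                    f_fret_true = f_true * ctx$gf)
      state <- emit_condition(state,
                              mixture_signals(ctx, spec, D, A, e_app, f_true),
                              well_role("mixture", donor_conc_nM = D,
                                        acceptor_conc_nM = A))
    }
    finish_sim(state, ctx, list(scenario = "titration",
                                kd_nM = spec$kd_nM,
                                f_fret_max_RFU = spec$f_fret_max_RFU,
                                transfer_efficiency = e_tr))
  })
}

#' Solve the competitive two-equilibrium system
#'
#' Coupled mass-action equilibria `D + A <-> DA` (dissociation constant
#' `kd`) and `D + I <-> DI` (`ki`), with total concentrations `D`, `A`,
#' `I`. Solved by damped fixed-point iteration on free donor to a
#' relative tolerance of 1e-10 on the complex concentration.
#'
#' @param D_total,A_total,I_total total concentrations (same units).
#' @param kd,ki dissociation constants (same units as concentrations).
#' @param tol relative convergence tolerance on `[DA]`.
#' @param max_iter iteration cap.
#' @return list with `DA`, `DI`, `D_free`, `A_free`, `I_free`,
#'   `iterations`.
#' @export
solve_competitive <- function(D_total, A_total, I_total, kd, ki,
                              tol = 1e-10, max_iter = 10000L) {
  if (any(c(D_total, A_total, I_total) < 0) || kd <= 0 || ki <= 0)
    fq_validation_error("concentrations must be >= 0 and constants > 0")
  df <- D_total / (1 + A_total / kd + I_total / ki)  # no-depletion start
  da_old <- Inf
  for (it in seq_len(max_iter)) {
    target <- D_total / (1 + A_total / (kd + df) + I_total / (ki + df))
    df <- 0.5 * df + 0.5 * target
    da <- df * A_total / (kd + df)
    if (is.finite(da_old) &&
        abs(da - da_old) <= tol * max(da, .Machine$double.eps))
      break
    da_old <- da
    if (it == max_iter)
      fq_stop("competitive equilibrium solve did not converge", "fq_solver_error")
  }
  da <- df * A_total / (kd + df)
  di <- df * I_total / (ki + df)
  list(DA = da, DI = di, D_free = df, A_free = A_total - da,
       I_free = I_total - di, iterations = it)
}

#' Simulate the inhibitor-screening plate
#'
#' Control mixtures (donor + acceptor, no inhibitor) plus one condition
#' per inhibitor dose, with the bound complex from the competitive
#' two-equilibrium solve ([solve_competitive()]). The per-complex
#' transfer efficiency is fixed so the uninhibited control shows the
#' configured apparent efficiency (`control_efficiency_pct`).
#'
#' @param spec a [simulation_spec()] with at least one inhibitor.
#' @return list with `scan` and `ledger`, as [simulate_titration()].
#' @export
simulate_screen <- function(spec = simulation_spec()) {
  if (length(spec$inhibitors) < 1L)
    fq_validation_error("simulate_screen needs at least one inhibitor")
  ctx <- sim_context(spec)
  D <- spec$screen_donor_nM; A <- spec$screen_acceptor_nM
  fb0 <- bound_complex(A, D, spec$kd_nM) / D
  e_tr <- (spec$control_efficiency_pct / 100) / fb0
  if (e_tr > 1)
    fq_validation_error("control_efficiency_pct unreachable: implied transfer efficiency > 1")
  sens_at <- function(e_app) ctx$sens_per_nM * D * e_app

  with_seed(spec$seed, {
    state <- new_sim_state(spec)
    state <- calibration_conditions(state, ctx, spec)
    e0 <- e_tr * fb0
    state$truth_row <- data.frame(condition = "control", f_bound = fb0,
                                  E_app = e0,
                                  f_fret_true = sens_at(e0) * ctx$gf)
    state <- emit_condition(state,
                            mixture_signals(ctx, spec, D, A, e0, sens_at(e0)),
                            well_role("mixture", donor_conc_nM = D,
                                      acceptor_conc_nM = A))
    for (inh in spec$inhibitors) {
      for (dose in inh$doses_uM) {
        eq <- solve_competitive(D, A, dose * 1000, spec$kd_nM,
                                inh$ki_uM * 1000)
        fb <- eq$DA / D
        e_app <- e_tr * fb
        state$truth_row <- data.frame(
          condition = sprintf("%s_%g", inh$id, dose), f_bound = fb,
          E_app = e_app, f_fret_true = sens_at(e_app) * ctx$gf)
        state <- emit_condition(
          state, mixture_signals(ctx, spec, D, A, e_app, sens_at(e_app)),
          well_role("mixture_inhibitor", donor_conc_nM = D,
                    acceptor_conc_nM = A, inhibitor_id = inh$id,
                    inhibitor_conc_uM = dose))
      }
    }
    finish_sim(state, ctx, list(scenario = "screen", kd_nM = spec$kd_nM,
                                transfer_efficiency = e_tr,
                                control_f_bound = fb0,
                                inhibitors = spec$inhibitors))
  })
}

#' Simulate a fluorophore-protein conjugate absorbance spectrum
#'
#' Beer-Lambert protein band at 280 nm plus the dye's absorbance band
#' scaled by the true degree of labeling, including the dye's 280-nm
#' bleed so the labeling-ratio arithmetic is exercised end to end.
#' [fp_ratio()] applied to the output recovers `fp_true` exactly in the
#' noiseless case.
#'
#' @param fluor [fluorophore_params()] of the dye.
#' @param protein_eps280 protein extinction coefficient at 280 nm.
#' @param fp_true true fluorophore-to-protein molar ratio.
#' @param protein_conc_M molar protein concentration.
#' @param grid_nm wavelength grid covering 280 nm and the dye maximum.
#' @param pathlength_cm cuvette path length.
#' @param noise_cv optional multiplicative noise CV.
#' @param n_scans number of replicate scans to generate.
#' @param seed seed used when `noise_cv > 0`.
#' @return an [absorbance_spectrum()] (or list of them if `n_scans > 1`).
#' @export
simulate_conjugate_absorbance <- function(fluor, protein_eps280, fp_true,
                                          protein_conc_M,
                                          grid_nm = seq(240, 700, by = 1),
                                          pathlength_cm = 1, noise_cv = 0,
                                          n_scans = 1, seed = 1) {
  if (fp_true < 0 || protein_conc_M <= 0 || protein_eps280 <= 0)
    fq_validation_error("inputs must be positive (fp_true >= 0)")
  protein_band <- bigauss(grid_nm, 280, 40, 0)
  dye_band <- bigauss(grid_nm, fluor$ex_max_nm, fluor$abs_fwhm_nm,
                      fluor$abs_asymmetry)
  a_max <- fp_true * protein_conc_M * fluor$extinction_at_max * pathlength_cm
  base <- protein_eps280 * protein_conc_M * pathlength_cm * protein_band +
    a_max * dye_band + fluor$a280_correction * a_max * protein_band
  mk <- function(noise) absorbance_spectrum(grid_nm, base * noise, pathlength_cm)
  if (noise_cv <= 0) {
    scans <- replicate(n_scans, mk(1), simplify = FALSE)
  } else {
    sdl <- sqrt(log(1 + noise_cv^2))
    scans <- with_seed(seed, replicate(n_scans, {
      mk(stats::rlnorm(length(grid_nm), -sdl^2 / 2, sdl))
    }, simplify = FALSE))
  }
  if (n_scans == 1L) scans[[1L]] else scans
}

#' Write a simulated plate scan and its ground-truth ledger
#'
#' Emits the documented plate-scan format; when the input is a simulator
#' result, the ground-truth ledger is written alongside as
#' `<path>.ledger.json`.
#'
#' @param x a [plate_scan()] or the list returned by
#'   [simulate_titration()] / [simulate_screen()].
#' @param path output path for the plate-scan file.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(x, path) {
  if (inherits(x, "plate_scan")) {
    write_plate_scan(x, path)
  } else {
    write_plate_scan(x$scan, path)
    jsonlite::write_json(x$ledger, paste0(path, ".ledger.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
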