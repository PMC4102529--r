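test_that("emission bands are linear, symmetric and grid-checked", {
  sh <- band_shape(520, 35, asymmetry = 0, amplitude_per_nM = 12)
  grid <- 400:650
  expect_equal(emission_band(sh, 0, grid)$intensities, rep(0, length(grid)))
  b1 <- emission_band(sh, 50, grid)
  b2 <- emission_band(sh, 100, grid)
  expect_equal(b2$intensities, 2 * b1$intensities)
  # symmetry about the peak when asymmetry is zero
  for (d in c(5, 10, 20)) {
    expect_equal(b1$intensities[grid == 520 - d],
                 b1$intensities[grid == 520 + d])
  }
  expect_equal(max(b1$intensities), 12 * 50)
  expect_equal(grid[which.max(b1$intensities)], 520)
  # asymmetric band: red side heavier
  ba <- emission_band(band_shape(520, 35, asymmetry = 0.3), 50, grid)
  expect_gt(ba$intensities[grid == 545], ba$intensities[grid == 495])
  expect_error(emission_band(sh, 10, 480:560), class = "fq_range_error")
  expect_error(band_shape(520, -1), class = "fq_validation_error")
})

test_that("simulation output is bit-identical under a fixed seed", {
  s1 <- simulate_titration(quick_spec(noise_cv = 0.02))
  s2 <- simulate_titration(quick_spec(noise_cv = 0.02))
  p1 <- withr::local_tempfile(); p2 <- withr::local_tempfile()
  write_fixture(s1, p1); write_fixture(s2, p2)
  expect_identical(readLines(p1), readLines(p2))
  # ledger sidecar written alongside, carrying the seed
  lg <- jsonlite::read_json(paste0(p1, ".ledger.json"))
  expect_equal(lg$seed, 42)
  expect_equal(lg$crosstalk_a, 0.129)
  # a different seed changes the noisy intensities
  s3 <- simulate_titration(quick_spec(noise_cv = 0.02, seed = 43))
  expect_false(identical(s1$scan$spectra[[20]]$intensities,
                         s3$scan$spectra[[20]]$intensities))
})

test_that("generator fixtures round-trip through the plate format", {
  sim <- simulate_titration(quick_spec())
  p <- withr::local_tempfile()
  write_fixture(sim, p)
  back <- read_plate_scan(p)
  expect_equal(length(back$spectra), length(sim$scan$spectra))
  expect_equal(nrow(back$layout), nrow(sim$scan$layout))
  w <- sim$scan$layout$well_id[10]
  expect_equal(get_spectrum(back, w, 470)$intensities,
               get_spectrum(sim$scan, w, 470)$intensities, tolerance = 1e-7)
})

test_that("noiseless pipeline extraction matches the generator ground truth", {
  spec <- quick_spec()
  sim <- simulate_titration(spec)
  decomp <- decompose_titration(sim$scan)
  truth <- unique(sim$ledger$wells[!is.na(sim$ledger$wells$f_fret_true),
                                   c("condition", "f_fret_true")])
  truth_f <- truth$f_fret_true[match(sprintf("titration_%g", decomp$acceptor_nM),
                                     truth$condition)]
  # F_FRET equals f_max * bound / D at every concentration
  expect_equal(decomp$F_FRET, truth_f, tolerance = 1e-8)
  # zero-acceptor wells give exactly zero FRET signal
  expect_lt(abs(decomp$F_FRET[decomp$acceptor_nM == 0]), 1e-6)
  # monotone in the generated bound fraction
  expect_true(all(diff(decomp$F_FRET) > 0))
})

test_that("pipeline estimates are invariant under the instrument gain", {
  r1 <- kd_workflow(simulate_titration(quick_spec())$scan)
  # doubled gain: all intensities double, Kd/a/b unchanged, F_max doubles
  r2 <- kd_workflow(simulate_titration(quick_spec(gain = 200))$scan)
  expect_equal(r2$fit$kd_nM, r1$fit$kd_nM, tolerance = 1e-8)
  expect_equal(r2$factors$a, r1$factors$a, tolerance = 1e-10)
  expect_equal(r2$factors$b, r1$factors$b, tolerance = 1e-10)
  expect_equal(r2$fit$f_max, 2 * r1$fit$f_max, tolerance = 1e-6)
  # doubled photon budget at fixed gain rescales the donor/acceptor
  # bands but leaves every estimated quantity intact
  r3 <- kd_workflow(simulate_titration(
    quick_spec(rfu_per_absorbance = 4e7))$scan)
  expect_equal(r3$fit$kd_nM, r1$fit$kd_nM, tolerance = 1e-8)
  expect_equal(r3$fit$f_max, r1$fit$f_max, tolerance = 1e-6)

  e1 <- analyze_screen(simulate_screen(quick_spec())$scan)
  e2 <- analyze_screen(simulate_screen(quick_spec(gain = 200))$scan)
  expect_equal(e2$control$efficiency_pct, e1$control$efficiency_pct,
               tolerance = 1e-8)
})

test_that("the competitive equilibrium solve matches a brute-force root", {
  # independent oracle: scalar root-finding on free donor
  brute <- function(D, A, I, kd, ki) {
    g <- function(df) df * (1 + A / (kd + df) + I / (ki + df)) - D
    df <- stats::uniroot(g, c(0, D), tol = 1e-14)$root
    df * A / (kd + df)
  }
  set.seed(12)
  for (i in 1:100) {
    D <- runif(1, 1, 500); A <- runif(1, 0, 2000); I <- runif(1, 0, 1e5)
    kd <- 10^runif(1, -1, 3); ki <- 10^runif(1, -1, 5)
    got <- solve_competitive(D, A, I, kd, ki)$DA
    want <- brute(D, A, I, kd, ki)
    expect_equal(got, want, tolerance = 1e-6)
  }
  # conservation holds exactly
  eq <- solve_competitive(100, 100, 200, 17.93, 7.42)
  expect_equal(eq$DA + eq$DI + eq$D_free, 100, tolerance = 1e-8)

  # impotent inhibitor: no displacement
  expect_equal(solve_competitive(100, 100, 1e6, 17.93, 1e15)$DA,
               bound_complex(100, 100, 17.93), tolerance = 1e-8)
  # saturating dose: complex fully displaced
  expect_lt(solve_competitive(100, 100, 1e9, 17.93, 7.42)$DA, 1e-3)
  expect_error(solve_competitive(-1, 100, 0, 1, 1),
               class = "fq_validation_error")
})

test_that("saturating inhibitor doses drive measured inhibition to 100%", {
  spec <- quick_spec(inhibitors = list(
    list(id = "potent", ki_uM = 0.00742, doses_uM = c(0.2, 20, 2000, 2e5))))
  res <- analyze_screen(simulate_screen(spec)$scan)
  top <- res$records[res$records$dose_uM == 2e5, ]
  expect_gt(top$inhibition_pct, 99.9)
})

test_that("conjugate absorbance simulation honours its degenerate cases", {
  fl <- read_fluorophore_params()$alexa488
  ab0 <- simulate_conjugate_absorbance(fl, 430000, 0, 2e-6)
  # no dye band: absorbance near the dye maximum is essentially zero
  expect_lt(max(ab0$absorbance[ab0$wavelengths > 450]), 1e-6)
  expect_equal(fp_ratio(conjugate_spec("p", fl, ab0, 430000))$ratio, 0)
  expect_error(simulate_conjugate_absorbance(fl, 430000, 1, -1),
               class = "fq_validation_error")
})
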