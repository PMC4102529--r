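# donor-like band with an explicit red tail whose 570:520 point ratio is r
donor_like <- function(conc, r = 0.2, wl = 410:700, well = "D") {
  main <- exp(-(wl - 520)^2 / (2 * 14^2))
  tail_b <- exp(-(wl - 570)^2 / (2 * 18^2))
  cc <- (r * main[wl == 520] - main[wl == 570]) /
    (tail_b[wl == 570] - r * tail_b[wl == 520])
  emission_spectrum(well, 470, wl, conc * (main + cc * tail_b))
}

acceptor_like <- function(conc, wl = 410:700, ex = 530, scale = 1, well = "A") {
  band <- exp(-(wl - 570)^2 / (2 * ifelse(wl < 570, 7, 20)^2))
  emission_spectrum(well, ex, wl, scale * conc * band)
}

test_that("ratio factor a is a scale-invariant bleed-through estimate", {
  # concentration-scaled copies of one spectrum: identical ratio, rms 0
  out <- ratio_factor_a(lapply(c(100, 200, 300), donor_like, r = 0.2))
  expect_equal(out$rms, 0, tolerance = 1e-12)
  expect_equal(out$n, 3L)
  # window means differ slightly from the point ratio; stay within 1%
  expect_equal(out$a, 0.2, tolerance = 0.01)

  # no emission beyond 560 nm -> a = 0
  wl <- 410:700
  blue <- emission_spectrum("D", 470, wl,
                            ifelse(wl > 560, 0, exp(-(wl - 520)^2 / 200)))
  expect_equal(ratio_factor_a(list(blue))$a, 0)

  flat0 <- emission_spectrum("D", 470, wl, rep(0, length(wl)))
  expect_error(ratio_factor_a(list(flat0)), class = "fq_degenerate_error")
  expect_error(ratio_factor_a(list()), class = "fq_validation_error")
})

test_that("ratio factor b is the direct-excitation ratio across a series", {
  concs <- c(100, 200, 300, 400, 500)
  exA <- lapply(concs, acceptor_like)
  ex470 <- lapply(concs, acceptor_like, ex = 470, scale = 0.101)
  out <- ratio_factor_b(ex470, exA)
  expect_equal(out$b, 0.101, tolerance = 1e-12)
  expect_equal(out$rms, 0, tolerance = 1e-12)
  expect_equal(out$n, 5L)

  # zero acceptor absorbance at the donor wavelength -> b = 0
  zero470 <- lapply(concs, acceptor_like, ex = 470, scale = 0)
  expect_equal(ratio_factor_b(zero470, exA)$b, 0)

  expect_error(ratio_factor_b(ex470[1:3], exA), class = "fq_validation_error")
  expect_warning(ratio_factor_b(exA, exA), "b >= 1")
})

test_that("FRET signal decomposition is exact linear bookkeeping", {
  f <- ratio_factors(0.129, 0.101)
  expect_equal(fret_signal(1000, 2000, 3000, f), 439)
  # no-FRET identity
  expect_equal(fret_signal(0.129 * 50 + 0.101 * 80, 50, 80, f), 0)
  # zero factors pass the raw signal through
  expect_equal(fret_signal(1234, 999, 888, ratio_factors(0, 0)), 1234)

  # linearity in each argument over random draws
  set.seed(3)
  for (i in 1:20) {
    x <- runif(3, 0, 5000); y <- runif(3, 0, 5000)
    expect_equal(fret_signal(x[1] + y[1], x[2] + y[2], x[3] + y[3], f),
                 fret_signal(x[1], x[2], x[3], f) +
                   fret_signal(y[1], y[2], y[3], f))
  }
  expect_error(fret_signal(Inf, 1, 1, f), class = "fq_validation_error")
})

test_that("ratio factor constructor rejects unphysical values", {
  expect_error(ratio_factors(1.2, 0.1), class = "fq_validation_error")
  expect_error(ratio_factors(0.1, -0.1), class = "fq_validation_error")
  expect_error(ratio_factors(0.1, 0.1, a_rms = -1), class = "fq_validation_error")
})

test_that("efficiency estimator returns zero without sensitization and is
           scale-free", {
  don <- donor_like(100)
  accA <- acceptor_like(100)
  acc470 <- acceptor_like(100, ex = 470, scale = 0.101)
  # mixture = donor bleed + direct acceptor only
  mix <- don
  mix$intensities <- don$intensities + acc470$intensities
  e0 <- fret_efficiency(mix, don, acc470, accA, A_D = 0.005, A_A = 0.001)
  expect_equal(e0$E_pct, 0, tolerance = 1e-10)

  # add sensitized emission: efficiency becomes positive and is invariant
  # under common intensity scaling of all four spectra
  sens <- acceptor_like(100, ex = 470, scale = 0.3)
  mix$intensities <- mix$intensities + sens$intensities
  e1 <- fret_efficiency(mix, don, acc470, accA, A_D = 0.005, A_A = 0.001)
  expect_gt(e1$E_pct, 0)
  dbl <- function(s) { s$intensities <- 2 * s$intensities; s }
  e2 <- fret_efficiency(dbl(mix), dbl(don), dbl(acc470), dbl(accA),
                        A_D = 0.005, A_A = 0.001)
  expect_equal(e2$E_pct, e1$E_pct, tolerance = 1e-12)

  # degenerate direct reference
  zero <- acceptor_like(100, ex = 470, scale = 0)
  expect_error(fret_efficiency(mix, don, zero, accA, A_D = 0.005, A_A = 0.001),
               class = "fq_degenerate_error")
  expect_error(fret_efficiency(mix, don, acc470, accA, A_D = 0, A_A = 0.001),
               class = "fq_validation_error")
})

test_that("generated mixtures round-trip the target efficiency", {
  spec <- quick_spec()
  sim <- simulate_screen(spec)
  res <- analyze_screen(sim$scan, config = screen_config())
  expect_equal(res$control$efficiency_pct, 53.51, tolerance = 1e-8)
})
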