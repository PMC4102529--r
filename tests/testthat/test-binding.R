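test_that("bound complex takes the physical quadratic root", {
  expect_equal(bound_complex(0, 100, 20), 0)
  # stoichiometric limit as kd -> 0+
  expect_equal(bound_complex(250, 100, 1e-9), 100, tolerance = 1e-6)
  expect_equal(bound_complex(40, 100, 1e-9), 40, tolerance = 1e-6)
  # closed form at A = D = kd = k: [DA] = k (3 - sqrt(5)) / 2
  for (k in c(1, 17.93, 400)) {
    expect_equal(bound_complex(k, k, k), k * (3 - sqrt(5)) / 2,
                 tolerance = 1e-12)
  }
  expect_error(bound_complex(-1, 100, 20), class = "fq_validation_error")
  expect_error(bound_complex(1, 100, 0), class = "fq_validation_error")
})

test_that("bound complex satisfies mass action and symmetry on random inputs", {
  set.seed(7)
  n <- 1000
  A <- runif(n, 0.01, 2000); D <- runif(n, 0.01, 2000)
  kd <- 10^runif(n, -2, 4)
  da <- bound_complex(A, D, kd)
  expect_true(all(da >= 0 & da <= pmin(A, D) + 1e-9))
  # ([D_free][A_free]) / [DA] == kd
  kd_back <- (D - da) * (A - da) / da
  expect_equal(kd_back, kd, tolerance = 1e-6)
  # symmetry in the two totals
  expect_equal(bound_complex(D, A, kd), da, tolerance = 1e-12)
})

test_that("predicted FRET saturates monotonically at f_max", {
  expect_equal(predicted_fret(0, 100, 20, 6330), 0)
  expect_equal(predicted_fret(1e9, 100, 17.93, 6330), 6330, tolerance = 1e-4)
  expect_equal(predicted_fret(50, 50, 50, 1000), 1000 * (3 - sqrt(5)) / 2,
               tolerance = 1e-9)
  y <- predicted_fret(seq(0, 2000, by = 50), 100, 17.93, 6330)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0 & y <= 6330))
  expect_error(predicted_fret(10, 0, 20, 100), class = "fq_validation_error")
})

test_that("the binding fit recovers generating parameters", {
  A <- paper_design_A
  y <- predicted_fret(A, 100, 17.93, 6330)
  fit <- fit_binding(titration_series(A, y, 100))
  # noiseless: recovery to well beyond 4 significant figures
  expect_equal(fit$kd_nM, 17.93, tolerance = 1e-6)
  expect_equal(fit$f_max, 6330, tolerance = 1e-6)
  expect_equal(fit$adj_r_squared, 1, tolerance = 1e-10)
  expect_true(fit$converged)

  # 2% multiplicative noise, seeded: kd within 10%, adj R2 > 0.98
  set.seed(21)
  y_noisy <- y * exp(rnorm(length(y), 0, 0.02))
  fitn <- fit_binding(titration_series(A, y_noisy, 100))
  expect_lt(abs(fitn$kd_nM - 17.93) / 17.93, 0.10)
  expect_gt(fitn$adj_r_squared, 0.98)
})

test_that("kd is invariant under rescaling of the signal", {
  A <- paper_design_A
  set.seed(4)
  y <- predicted_fret(A, 100, 17.93, 6330) * exp(rnorm(12, 0, 0.01))
  f1 <- fit_binding(titration_series(A, y, 100))
  f2 <- fit_binding(titration_series(A, y * 37.5, 100))
  expect_equal(f2$kd_nM, f1$kd_nM, tolerance = 1e-6)
  expect_equal(f2$f_max, 37.5 * f1$f_max, tolerance = 1e-6)
})

test_that("degenerate titrations are reported, not silently fitted", {
  A <- paper_design_A
  expect_error(fit_binding(titration_series(A, rep(0, 12), 100)),
               class = "fq_degenerate_error")
  expect_error(fit_binding(titration_series(c(0, 10, 25), c(0, 1, 2), 100)),
               class = "fq_validation_error")
  # saturated everywhere: non-identifiable design -> error or unbounded se
  res <- tryCatch(fit_binding(titration_series(A, rep(5000, 12), 100)),
                  error = function(e) e)
  if (inherits(res, "binding_fit")) {
    expect_true(any(res$at_bounds) || !is.finite(res$kd_se_nM) ||
                  res$kd_se_nM > res$kd_nM)
  } else {
    expect_s3_class(res, "fretquant_error")
  }
})

test_that("titration series validation catches malformed input", {
  expect_error(titration_series(c(0, 10, 10), 1:3, 100),
               class = "fq_validation_error")
  expect_error(titration_series(c(-5, 10, 20), 1:3, 100),
               class = "fq_validation_error")
  expect_error(titration_series(c(0, 10, 20), 1:2, 100),
               class = "fq_validation_error")
  expect_error(titration_series(c(0, 10, 20), 1:3, 0),
               class = "fq_validation_error")
})

test_that("bootstrap intervals are reproducible and honest", {
  A <- paper_design_A
  set.seed(2)
  reps <- lapply(predicted_fret(A, 100, 17.93, 6330),
                 function(m) m * exp(rnorm(9, 0, 0.02)))
  s <- titration_series(A, vapply(reps, mean, 0), 100, replicates = reps)
  b1 <- bootstrap_ci(s, n_boot = 150, seed = 9)
  b2 <- bootstrap_ci(s, n_boot = 150, seed = 9)
  expect_identical(b1$kd_ci, b2$kd_ci)
  expect_true(b1$kd_ci[1] < 17.93 && b1$kd_ci[2] > 17.93)
  expect_error(bootstrap_ci(s, n_boot = 50, seed = 1),
               class = "fq_validation_error")

  # noiseless replicates: interval width collapses
  s0 <- titration_series(A, predicted_fret(A, 100, 17.93, 6330), 100,
                         replicates = lapply(
                           predicted_fret(A, 100, 17.93, 6330), rep, times = 3))
  b0 <- bootstrap_ci(s0, n_boot = 100, seed = 1)
  expect_lt(diff(b0$kd_ci), 1e-6)
})

test_that("bootstrap 95% intervals cover the generating kd", {
  # coverage study: simulated experiments at the titration design
  set.seed(31)
  n_exp <- 60
  covered <- 0L
  for (i in seq_len(n_exp)) {
    reps <- lapply(predicted_fret(paper_design_A, 100, 17.93, 6330),
                   function(m) m * exp(rnorm(9, 0, 0.02)))
    s <- titration_series(paper_design_A, vapply(reps, mean, 0), 100,
                          replicates = reps)
    ci <- bootstrap_ci(s, n_boot = 120, seed = i)$kd_ci
    if (ci[1] <= 17.93 && ci[2] >= 17.93) covered <- covered + 1L
  }
  expect_gte(covered / n_exp, 0.85)
})
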