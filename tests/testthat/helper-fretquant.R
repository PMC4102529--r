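# Shared fixture builders; everything is generated in code.

# bare spectrum on an integer grid starting at 500 nm
toy_spectrum <- function(intensities, wl = seq(500, by = 1,
                                               length.out = length(intensities)),
                         ex = 470, well = "T1") {
  emission_spectrum(well, ex, wl, intensities)
}

# small, fast simulation: 2 replicate wells per condition, noiseless
quick_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_samples = 1, n_reads = 2, noise_cv = 0, seed = 42)
  do.call(simulation_spec, utils::modifyList(defaults, args))
}

# the titration design: 12 acceptor concentrations, donor 100 nM
paper_design_A <- c(0, 10, 25, 50, 75, 100, 150, 250, 400, 700, 1100, 1600)

expect_rel_equal <- function(actual, expected, rel_tol) {
  expect_lt(abs(actual - expected), rel_tol * abs(expected))
}
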