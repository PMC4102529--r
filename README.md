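# fretquant

Quantitative analysis of steady-state, in-solution FRET assays run on
multi-well plate readers: from raw wavelength-resolved emission scans to
cross-talk-corrected FRET signals, binding constants, and
inhibitor-screening reports.

The package targets the sensitized-emission workflow used to measure
protein–protein interactions such as LFA-1 binding its ligand ICAM-1: a
donor-dye conjugate (Alexa-488-like, emission ≈ 520 nm) is mixed with an
acceptor-dye conjugate (Alexa-555-like, emission ≈ 570 nm); complex
formation brings the dyes into Förster range and the acceptor channel
gains a sensitized component. It is written for assay developers and
screening groups who need the full quantitative chain — not just a peak
reader — including honest replicate statistics and uncertainty.

## What it computes

**Cross-talk correction.** The acceptor-channel intensity under donor
excitation, `F_DA`, mixes three things. Two ratio factors calibrate the
contaminations from dedicated single-dye wells:
`a` = donor-only emission at 570 nm over its 520 nm peak (bleed-through),
`b` = acceptor-only emission at 570 nm under donor excitation over the
same reading under acceptor-band excitation (direct excitation). The
FRET signal is then

    F_FRET = F_DA − a·F_D − b·F_A

**Binding constant.** With donor total `D` fixed and acceptor total `A`
titrated, the one-to-one complex with ligand depletion follows the
mass-action quadratic

    [DA] = ((A + D + Kd) − sqrt((A + D + Kd)² − 4AD)) / 2

and `F_FRET = F_FRETmax · [DA]/D` is fitted for `(Kd, F_FRETmax)` by
bounded, multi-start Levenberg–Marquardt, with Jacobian standard errors,
adjusted R², and a case-resampling bootstrap over replicates.

**FRET efficiency and screening.** A sensitized-emission estimator
integrates the 560–610 nm window, removes donor bleed (scaled donor-only
reference) and direct acceptor emission (acceptor-only reference), and
normalizes by the acceptor's direct emission and the absorbance ratio
`A^A/A^D` at the donor excitation wavelength. Competitive inhibitors are
ranked per dose by inhibition efficiency
`100·(F_control − F_x)/F_control` with Student-t significance codes.

**Photophysics.** Degrees of labeling (F/P ratios) from conjugate
absorbance via `F/P = Amax/(ε·l·[protein])` with 280-nm dye-bleed
correction, and acceptor-to-donor fluorophore (A/D) ratios.

**Synthetic data.** A physically structured generator
(`simulate_titration()`, `simulate_screen()`,
`simulate_conjugate_absorbance()`) emits complete plates — emission
bands, binding equilibria solved exactly, competitive inhibition by a
damped fixed-point equilibrium solver, cross-talk, background, and
3 samples × 3 reads of log-normal replicate noise — together with a
ground-truth ledger, so every pipeline stage is testable without
instrument data.

## Worked example

```r
library(fretquant)

# a full titration plate at the published design: donor 100 nM, acceptor
# 0-1600 nM, Kd 17.93 nM, F_FRETmax 6330 RFU, 2% replicate noise
sim <- simulate_titration(simulation_spec(seed = 1))
res <- kd_workflow(sim$scan)
print(res)
#> <ratio_factors> a = 0.1285 +/- 0.0009 (n=3), b = 0.1009 +/- 0.0005 (n=5)
#> One-to-one ligand-depletion binding fit
#>   Kd      = 17.35 +/- 0.853 nM
#>   F_max   = 6311 +/- 31.9 RFU
#>   adj R^2 = 0.9994  (n = 12 points)

bootstrap_ci(res$series, n_boot = 500, seed = 1)$kd_ci
#> [1] 14.21... 20.89...
```

The calibrated factors land on the generating values (a = 0.129,
b = 0.101) within replicate noise, and the fitted `Kd` recovers the
generating 17.93 nM within its standard error; with `noise_cv = 0` the
recovery is exact. A screening plate works the same way:

```r
scr <- analyze_screen(simulate_screen(simulation_spec(seed = 1))$scan)
print(scr)
#> FRET inhibitor screen: control efficiency 52.90% +/- 0.84 (n = 9)
#>   inhibitor_id dose_uM fret_efficiency_pct inhibition_pct stars rank_at_dose
#>     lovastatin   2e-01               15.29          71.11    **            1
#>  CD11a_237-261   2e-01               49.74           5.98    **            2
#>  ...
```

Inhibition rises monotonically with dose and the per-dose ranking
follows the generated inhibition constants. A thin command-line wrapper
(`inst/cli/fretquant.R`) exposes the same workflows as `simulate`, `kd`,
`screen`, `fpratio` and `efficiency` subcommands.

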