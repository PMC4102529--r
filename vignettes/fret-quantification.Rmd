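---
title: "Quantifying in-solution FRET: models, estimators and the synthetic assay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying in-solution FRET: models, estimators and the synthetic assay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretquant)
```

# The assay and its observables

A steady-state sensitized-emission FRET assay measures a bimolecular
protein interaction in solution. A donor-dye protein conjugate (emission
peak near 520 nm, excited near 470 nm) is mixed with an acceptor-dye
conjugate (emission near 570 nm, excited near 530 nm). When the proteins
bind, the dyes come within Förster distance and three things happen in
the spectra: the donor peak is quenched, the acceptor peak gains a
sensitized component under donor excitation, and the acceptor's direct
emission is unchanged. The plate reader delivers, per well,
wavelength-resolved emission under each excitation.

Three readings summarize a mixture well:

* `F_D` — donor-peak intensity under donor excitation,
* `F_DA` — acceptor-peak intensity under donor excitation,
* `F_A` — acceptor-peak intensity under acceptor-band excitation.

`F_DA` is contaminated by donor bleed-through and by direct acceptor
excitation at the donor wavelength. Both contaminations are proportional
to signals we can measure independently, which is the whole trick of the
correction.

# Cross-talk ratio factors

From donor-only wells, `a` is the ratio of the 570 nm to the 520 nm
reading under donor excitation; from acceptor-only wells scanned under
both excitations, `b` is the 570 nm reading under donor excitation over
the same reading under acceptor-band excitation. Both are intensity
ratios of one species, hence concentration- and gain-invariant; the
package estimates each as the mean over a calibration concentration
series (three donor-only, five acceptor-only concentrations in the
default design) and quotes the rms across the series. Factors are
calibrated once per plate from dedicated wells and applied plate-wide;
per-well recalibration is not attempted, because the factors are dye
properties, not well properties. The FRET signal of a mixture well is
then the linear bookkeeping

$$F_\mathrm{FRET} = F_{DA} - a\,F_D - b\,F_A,$$

where `F_D` is read in the mixture itself, so donor quenching is
automatically accounted for. Negative `F_FRET` values — possible at zero
acceptor or under noise — are deliberately retained for fitting, because
truncating at zero biases the binding amplitude and hence the
dissociation constant upward; clipping to `[0, 100]` happens only in
printed reports (`clip_pct()`).

## Reading "the intensity at 520 nm"

Instrument grids may be offset by 1–2 nm from the nominal peak
positions, and a single-pixel read is fragile. `peak_intensity()`
therefore averages over a ±2 nm window (trapezoid-weighted; half-width
configurable via `analysis_windows()`), reducing to linear interpolation
at half-width zero. All band integrals use the trapezoidal rule with
linearly interpolated endpoints, which makes integrals exactly additive
over adjacent windows. Wavelength grids are never silently resampled —
a grid mismatch between a spectrum and its blank is an error, since
silent interpolation hides acquisition mistakes.

# FRET efficiency estimator

The efficiency of the mixture is estimated from spectral integrals over
the 560–610 nm window under donor excitation:

$$E = 100\cdot\frac{A^A}{A^D}\cdot
      \frac{\int\!\left(f_{DA} - s_D f_D - f_A^{470}\right)}
           {\int f_A^{470}},$$

where `f_DA` is the mixture spectrum, `f_D` the donor-only reference
scaled by `s_D` (the ratio of the mixture's 520 nm reading to the
reference's, i.e. the surviving donor fraction), `f_A^470` the
acceptor-only spectrum under donor excitation, and `A^D`, `A^A` the
absorbances of donor and acceptor at the donor excitation wavelength.
The numerator is the sensitized emission; dividing by the acceptor's
direct emission and multiplying by the absorbance ratio converts "extra
acceptor photons" into "fraction of donor excitations transferred".

Two notes on this estimator. First, it is a reconstruction of the
sensitized-emission (ratio-A) method; the exact algebra used by any
given instrument workflow varies, so the estimator is isolated in the
single function `fret_efficiency()` and can be swapped without touching
callers. Second, the acceptor absorbs only weakly at the donor
wavelength, where direct absorbance measurements are unreliable; the
package therefore infers `A^A` as `b · ε_A(λ_A)·[A]·l`, using the
measured cross-talk factor — by definition the ratio of direct-excitation
efficiencies — which keeps the estimator exactly consistent with the
acceptor-only reference scan it subtracts.

The acceptor excitation wavelength is configuration
(`analysis_windows(acceptor_ex_nm = )`, default 530 nm); instruments are
operated anywhere in the acceptor band (530 and 540 nm are both common)
and the configured value is authoritative.

# Binding model

With total donor `D` fixed and total acceptor `A` titrated, a one-to-one
complex at equilibrium satisfies the mass-action quadratic; at the
concentrations where FRET assays operate (tens of nM, near the
dissociation constant itself) free-ligand approximations fail, so the
ligand-depletion root is used directly:

$$[DA] = \tfrac12\!\left((A + D + K_d) -
        \sqrt{(A + D + K_d)^2 - 4AD}\right),$$

evaluated as `2AD / (s + sqrt(s² − 4AD))` to avoid catastrophic
cancellation at weak binding. The measured signal is assumed
proportional to the bound donor fraction,
`F_FRET = F_FRETmax·[DA]/D`, which saturates at `F_FRETmax` when every
donor is complexed.

`fit_binding()` estimates `(Kd, F_FRETmax)` by bounded
Levenberg–Marquardt (via `minpack.lm`). The saturation tail of this
model is flat, and a single bad start for `Kd` can strand the optimizer
there, so initialization is multi-start: `F_FRETmax` starts at the
largest observation, `Kd` at the half-maximum concentration (linear
interpolation) and at five log-spaced values a decade either side.
Bounds are `Kd ∈ (10⁻³, 10⁶) nM` and `F_FRETmax ∈ (0, 100×max)`;
hitting a bound is reported and marks the standard errors unbounded
rather than quoting a meaningless Jacobian. Fits are unweighted by
default (matching how plain adjusted R² is usually quoted for such
titrations); inverse-variance weights can be passed explicitly. The
adjusted R² uses the fitted concentration points (`n` points, `p = 2`),
not the replicate-expanded count.

Uncertainty is reported two ways, because a quoted "± x nM" in assay
work is ambiguous: the Jacobian standard error from the fit, and a
case-resampling bootstrap (`bootstrap_ci()`) that resamples
replicate-level points within each concentration and refits.

# Screening analytics

The inhibition efficiency of a competitor at one dose is
`100·(F_control − F_x)/F_control`, with the control the uninhibited
mixture on the same plate. Efficiencies are computed per replicate well
and then averaged; the mean equals the mean-based value, but the
replicate spread feeds the significance tests honestly. The propagated
rms uses the first-order expression
`100·(f_x/f_c)·sqrt((σ_c/f_c)² + (σ_x/f_x)²)`. Apparent enhancers
(negative inhibition) are flagged, not clipped. Conditions are compared
to the control by a two-sided Student t-test (equal variances by
default, Welch optional) with the conventional star coding (`*` p<0.05,
`**` p<0.005); no multiple-testing correction is applied by default —
per-dose tests are reported raw, as screening reports conventionally do
— with Holm correction available in `screen_config()`. IC50 fitting is
deliberately out of scope: the report presents per-dose inhibition, and
extracting inhibition constants from single-dose data would overreach.

# Degree of labeling

The F/P ratio of a conjugate comes from its absorbance spectrum:
`F/P = Amax/(ε·l·[protein])`, with `Amax` the maximum within ±5 nm of
the dye's nominal absorbance peak (tolerating conjugation-induced
shifts) and `[protein]` from the 280 nm absorbance after subtracting the
dye's 280-nm bleed (`a280_correction · Amax`). Dye constants — peak
positions, extinction coefficients, quantum yields, 280-nm corrections —
ship as an editable configuration file
(`inst/extdata/fluorophores.tsv`, Alexa-488-like: ε ≈ 71,000 M⁻¹cm⁻¹,
a280 ≈ 0.11; Alexa-555-like: ε ≈ 150,000 M⁻¹cm⁻¹, a280 ≈ 0.08) and are
never hard-coded in a computation, so user-supplied constants reproduce
user results.

The A/D fluorophore ratio combines concentrations with labeling:
`A/D = ([A]·F/P_A)/([D]·F/P_D)`. It is computed from first principles;
note that published A/D sequences for this assay type are sometimes
internally inconsistent with simple proportionality (a fixed acceptor
and a 4× donor dilution must scale A/D by exactly 4), so printed A/D
tables are not used as a correctness oracle anywhere in the test suite —
nor is the reported efficiency-versus-A/D sequence, which is strongly
non-monotone in a way single-complex theory cannot produce.

# The synthetic assay

Real plate data for this workflow are rarely deposited, so the package
carries a generator whose defaults are the study design itself: donor
fixed at 100 nM; twelve acceptor concentrations from 0 to 1600 nM
(`0, 10, 25, 50, 75, 100, 150, 250, 400, 700, 1100, 1600` — chosen to
straddle the expected dissociation constant of 17.93 nM and reach
saturation); cross-talk factors 0.129 and 0.101; degrees of labeling
1.48 and 3.14; saturation amplitude 6.33×10³ RFU; three samples × three
reads per condition; 2% multiplicative log-normal noise plus a 50 RFU
additive background. The screen scenario fixes the equimolar 100 nM
mixture's apparent efficiency at 53.51% and includes a potent
lovastatin-like control (inhibition constant calibrated once, to
7.42 nM, so the lowest published dose of 0.2 µM produces its published
inhibition) plus three peptide competitors of graded potency.

## Forward model

Emission bands are bi-Gaussian (independent left/right widths; the mode
sits exactly at the nominal peak, and zero asymmetry gives an exactly
symmetric band — properties a skew-normal parameterization lacks without
mode correction, which is why bi-Gaussian was chosen). Amplitudes follow
a photon budget: peak signal = (instrument scale) × gain × absorbance at
the excitation wavelength × quantum yield, with absorbances from the
dyes' configured extinction coefficients and band models times the
labeling degree. Every emitted intensity is linear in the gain
parameter, so gain invariance of `a`, `b`, efficiencies, F/P and the
dissociation constant is a generator-verifiable pipeline property.

For a titration point, the bound complex comes from the exact quadratic
root; the donor band is quenched by the apparent efficiency
`E_tr·bound/D`; the sensitized band carries `F_FRETmax·bound/D` at the
acceptor peak; donor bleed-through is injected by adding a calibrated
red tail to the donor band, and acceptor direct excitation by emitting
the acceptor-only 470-nm band as `b` times its own-excitation band. The
per-complex transfer efficiency `E_tr` is derived from `F_FRETmax` and
the photon budget (and recorded in the ledger); requesting an amplitude
that would imply `E_tr > 1` is rejected as unphysical. For screens, the
bound complex under a competitive inhibitor comes from the coupled
two-equilibrium solve (`solve_competitive()`, damped fixed-point
iteration to 10⁻¹⁰ relative tolerance, tested against an independent
root-finding oracle).

The photon-budget scale deserves a note, because it controls the
assay's error budget. The acceptor's direct emission under donor
excitation grows linearly with acceptor concentration while the
sensitized signal saturates, so at the top of the titration the 470-nm
channel is dominated by background that the `b`-subtraction must remove;
multiplicative read noise on that background is what limits the
precision of the extracted FRET signal. The default scale ties the
6.33×10³ RFU saturation amplitude to a per-complex transfer efficiency
near 0.9 — appropriate for an optimized pair carrying ~2 acceptor
fluorophores per donor — which keeps that background within the error
budget a high-quality fit implies. Even so, with 2% per-read noise the
dissociation constant recovered from a single simulated experiment
scatters with a standard deviation around a tenth of its value across
seeds; the replicate-level bootstrap interval reflects exactly this.

One calibration detail is worth stating plainly: band amplitudes and the
donor tail are calibrated *in the package's own measurement convention*
(the ±2 nm window means at 520/570 nm on the emission grid), not at
isolated wavelengths. This makes noiseless parameter recovery exact
rather than exact-up-to-window-curvature, which is the property the
acceptance tests rely on; it is a statement about the generator's
bookkeeping, not about the estimators, which never see the calibration.

## What the generator does not emulate

Passing tests on synthetic plates show the pipeline's algebra,
statistics and numerics are right; they do not certify instrument
physics. Known idealizations: no photobleaching, inner-filter effects,
detector saturation or well-to-well spatial gradients; noise is
independent per wavelength (real read noise is partly correlated across
a scan); the donor is assumed not to be directly excited at the
acceptor excitation wavelength (the same assumption the analysis method
itself makes of the `F_A` scan); the 3×3 replicate structure is emitted
as nine replicate wells because the plate format carries no read index;
and the one-site competitive model drives inhibition to 100% at
saturating dose, whereas published dose series for this assay plateau
below that — matching such plateaus would need a partial/non-competitive
term the screening module deliberately does not fit.

The titration's `F_FRETmax` (6.33×10³ RFU) and the screen's control
efficiency (53.51%) are both honored as generator defaults but are
mutually inconsistent under a single instrument scale; they parameterize
the two scenarios independently, as they came from different
experiments.

# Numerical and interface choices

* Errors are classed conditions (`fq_validation_error`,
  `fq_format_error`, `fq_consistency_error`, `fq_range_error`,
  `fq_degenerate_error`, `fq_config_error`, `fq_fit_error`), so callers
  and the CLI can branch on failure modes; the CLI maps them to exit
  codes 2/3/4.
* The plate-scan format is deliberately minimal delimited text
  (`#key=value` headers plus one row per well × excitation ×
  wavelength) written canonically to 9 significant digits; write → read
  → write is byte-identical, which makes fixtures diffable.
* Degenerate inputs fail loudly: all-zero titrations, saturated
  (non-identifiable) designs, missing calibration or control wells,
  corrected A280 ≤ 0, and efficiency estimation without direct acceptor
  signal are all errors, not NaNs.
* Problem sizes in the test suite are the study design itself (12
  concentrations × 9 replicates, 291-point spectra); the bootstrap
  coverage study uses 60 simulated experiments × 120 draws, enough to
  detect gross miscalibration of the interval while keeping the suite
  quick.

# A worked run

```{r example}
sim <- simulate_titration(simulation_spec(seed = 1))
res <- kd_workflow(sim$scan)
res$factors
res$fit
```

```{r plot, fig.width = 6, fig.height = 4}
plot(res$fit)
```
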