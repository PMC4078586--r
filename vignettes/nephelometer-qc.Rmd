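---
title: "Humidity and gravimetric-equivalency quality control for passive nephelometer PM data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Humidity and gravimetric-equivalency quality control for passive nephelometer PM data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephqc)
```

## The measurement problem

A passive nephelometer reports PM concentration inferred from scattered
light. Two systematic biases separate its reading from the gravimetric PM2.5
concentration a filter sampler would report at the same place and time:

- **humidity bias** — hygroscopic particle growth inflates scattering at high
  relative humidity, and (less discussed) filter equilibration at moderate RH
  makes nephelometers *under*-read at very low humidity;
- **aerosol-equivalency bias** — factory calibration against a standard
  mineral test dust does not transfer to biomass smoke, and across several
  orders of magnitude of concentration the relationship between the
  (humidity-adjusted) reading and gravimetric mass is visibly nonlinear.

`nephqc` estimates and applies corrections for both, and ranks the candidate
correction strategies by how well they predict held-out gravimetric samples.

## Correction-factor models

The observed correction factor of a co-location pair is
`CF = neph / grav`, the ratio of the window-averaged nephelometer reading to
the co-located gravimetric concentration (`observed_cf()`). Two parametric
families are fit by ordinary least squares on their linearising scales
(`fit_cf()`):

| form | model | fitting scale |
|---|---|---|
| `chakrabarti` | `CF = a + b·RH²/(1−RH)` | CF on `RH²/(1−RH)` |
| `richards_log` | `ln CF = a + b·ln(1−RH)` | `ln CF` on `ln(1−RH)` |

RH is a **fraction in [0, 0.99] everywhere** inside the package. Percent
columns are detected and converted at ingest (`read_rh_log()`: any value
above 1.5 implies percent), and values are clamped at 0.99 because `1 − RH`
appears in denominators and logarithms; the clamp count is reported.

Fitting is unweighted — the field practice is a plain linear regression — and
uses *all* samples regardless of RH. The conventional 60 % RH threshold is a
*prediction-time* rule: with `use_threshold = TRUE`, CF is forced to 1 at
`RH ≤ 0.60` and the fitted curve applies above. Keeping one fit with two
application rules mirrors how published parameter tables report a single
(a, b) per equation with separate with/without-threshold error columns. The
threshold value (0.60) is a stored, overridable model field, not a constant
baked into the code. The package's own comparisons support applying the
models over the full RH range: the fitted CF drops below 1 at low RH, so
thresholding discards a real negative bias correction.

A `chakrabarti` model whose parameters make CF ≤ 0 anywhere on [0, 0.99] is
rejected as invalid at construction and at prediction; the log-linear form is
positive by construction.

## Gravimetric conversion

`fit_gravimetric()` relates humidity-adjusted nephelometric PM (HAN, the
reading divided by CF(RH)) to gravimetric PM2.5 with four forms: a
through-origin linear slope (the intercept is pinned to zero, matching the
traditional published fits), log-log, log-log plus a hinge spline, and
log-log plus a quadratic term. The hinge form

```
ln Grav = a + b·ln HAN + c·max(ln HAN − d, 0)
```

activates its extra slope only above the knot `d`, capturing the flattening
of instrument response at high concentrations. The knot is chosen by
**exhaustive grid search over 7.5–12.0 in steps of 0.1** (on the `ln HAN`
scale, i.e. ≈1800–163,000 µg/m³), minimising the leave-one-out
cross-validated RMSE *on the original µg/m³ scale*; ties break to the
smallest knot so the search is deterministic. Knots with fewer than two
observations on either side are ineligible; a grid entirely outside the data
range degrades gracefully (warning, hinge coefficient zero).

Numerical choices worth stating:

- **Exact LOO by the hat identity.** For an OLS fit the leave-one-out linear
  predictor is `y_i − e_i/(1 − h_i)`; the grid search uses this closed form
  (one QR factorisation per knot) and is numerically identical to refitting
  each fold — the test suite checks it against independently coded
  brute-force loops to ~1e-9 relative error.
- **Plain exponential back-transformation.** Log-scale predictions are
  exponentiated without a retransformation (smearing) correction, matching
  the field convention the package follows; predictions are therefore
  conditional medians rather than means, a known conservative choice under
  lognormal errors.
- **Applicability range.** Prediction methods warn when inputs fall outside
  600–66,000 µg/m³, the nephelometric range over which such calibrations are
  observed; outside it the equations are extrapolation.

## One-step combined adjustment

Composing the log-linear CF with the log-log conversion eliminates the
intermediate HAN variable:

```
ln Grav = c0 + c1·ln(1 − RH) + c2·ln Neph [+ c3·max(ln Neph − knot, 0) | + c3·(ln Neph)²]
```

`fit_combined()` estimates this directly, with the same knot-search machinery
on the `ln Neph` scale. The combined family uses **no RH threshold
anywhere** — its appeal is exactly that it has one response (gravimetric
PM2.5), one reference value per sample, and no arbitrary cutoff. A published
preset ships the full log-linear coefficient set (3.102, 0.701, 0.717); the
spline variant's published record carries only the knot (8.1) and hinge
(−0.254), so that preset refuses to predict until refit on data.

Because Eq-5-style and Eq-8-style models both involve a hinge written with
clashing symbols in the field literature (the conversion's knot is called
*d*, while the combined form calls the knot *f* and the hinge coefficient
*d*), the package always stores the hinge coefficient as `c3` (or `c` for
conversion models) and the knot as `knot`/`d` fields — never reusing one
letter for two roles.

## Cross-validated model selection

`loo_cv()` is exhaustive leave-one-out: every sample in turn is held out,
the model refit on the remainder, and the squared error recorded on the
original concentration scale. `two_step_cv()` does the same with **both
stages retrained inside every fold** — CF fit on training pairs, training
readings adjusted, conversion fit on the adjusted pairs, and the held-out
reading passed sequentially through the fold's two models. Folds are the
samples themselves, so fold order is irrelevant and the result is invariant
to permutation (tested).

`comparison_table()` enumerates the fixed candidate set of 21 approaches:
3 one-step combined forms plus the 18 two-step combinations of
{quadratic-ratio CF with published ambient parameters, quadratic-ratio CF
refit, log-linear CF refit} × {with, without the 60 % threshold} ×
{log-log, log-log spline, log-log quadratic}. Through-origin linear
conversions are excluded from the table as uniformly dominated. The
published-parameter CF rows use the fixed set (1, 0.25) in every fold — that
approach has no free CF parameters — while its conversion stage is still
retrained per fold. Numbering is stable (1–3 combined; 4–12 without
threshold; 13–21 with), so approach ids are comparable across campaigns.

Two caveats the package makes explicit rather than hiding: CF-model CV error
is dimensionless (CF scale) while conversion and combined errors are in
µg/m³; and in-sample RSS is guaranteed monotone under nesting only on the
fitting (log) scale — original-scale CV RMSE need not be, which is precisely
why the knot is selected by CV rather than by in-sample fit.

## The synthetic campaign generator

`generate_campaign()` emulates a 65-pair co-location campaign
(`campaign_config()` defaults):

- latent true concentration `C` ~ log-uniform(600, 26,000) µg/m³ — the
  gravimetric range such campaigns span, two orders of magnitude;
- window RH ~ uniform(0.15, 0.95);
- instrument response `ln neph = α + β·ln C + ln CF(rh)` with defaults
  `α = −3.1, β = 1.4` and the log-linear CF truth (−0.72, −0.82);
- gravimetric reading `grav = C·exp(ε)`, `ε ~ N(0, σ²)`, `σ = 0.3` by
  default.

Choices and their reasons:

- **Multiplicative lognormal noise**, not additive: the concentrations span
  two orders of magnitude and every model here operates on the log scale.
- **β ≠ 1 by default** (β = 1.4, so the implied conversion slope is
  `1/β ≈ 0.714`, the magnitude seen in published calibration tables). The
  concentration-dependent power law is what makes the spline and quadratic
  forms non-trivial on synthetic data.
- **The measurement error is attached to the gravimetric reading**, with the
  nephelometer responding deterministically to the latent concentration.
  Algebraically this is the same forward model as putting the noise on the
  instrument, but it keeps the combined-regression truth exactly
  `c0 = −(α + a)/β`, `c1 = −b/β`, `c2 = 1/β`, so parameter-recovery tests
  have a closed-form target; if the noise sat in the regressor instead, OLS
  would be attenuation-biased and no finite-replication test could pin the
  truth. It is also a fair description of a field campaign, where filters
  have real measurement error (duplicate precision of order 10 %).
- **β = 1 is the "compatible data" regime** for the two-step/one-step
  identity: only then is the observed CF a pure function of RH, so both
  stages (and their composition) can fit noiseless data exactly. Structural
  identity tests therefore run at β = 1; with β = 1.4 the two-step model
  class is genuinely misspecified even without noise — itself an instructive
  property of the two-step approach.
- When the quadratic-ratio CF is fit on its linear scale under multiplicative
  lognormal noise, its population target is `(a, b)·exp(σ²/2)` (the lognormal
  mean), and recovery tests compare against that implied truth; the
  log-scale CF fit is unbiased for (a, b) directly.

What the generator does **not** emulate: aerosol physics (no κ-Köhler
hygroscopic growth curve — only the statistical CF form), instrument drift
or zeroing error, autocorrelated within-burn time structure in the
co-location averages, below-LOD censoring (samples are generated above LOD),
and any covariate effects (fuel/home/kitchen variables are carried but
inert, mirroring their non-significance in the adjustment models). Passing
tests on synthetic campaigns therefore demonstrate that the estimation
machinery is correct under the assumed error structure, not that the assumed
structure is the true physics of any particular field data set.

`generate_timeseries()` produces 10-second instrument logs — flat baseline,
exponential rise during active-flame windows (3-min time constant), slower
exponential decay afterwards (20 min), an RH profile per tick — for
demonstrating the ingestion and `apply` stages; it is a plumbing fixture,
not a combustion model.

## Field-data handling policies

- Filter mass gains are blank-corrected (default 2 µg) and converted with
  volume = flow × duration (default 4 L/min); net mass below the LOD
  (default 5 µg) flags the sample. Negative net mass truncates to zero
  concentration, flagged. Below-LOD samples are excluded from all model
  fitting by default (overridable) — their CF and log-concentration are not
  meaningful; exclusion is a policy of this package, since field practice
  varies.
- Duplicate precision is reported as the paired relative difference
  `|x1 − x2|/mean × 100` (mean over pairs; "relative SD" is the SD of the
  per-pair values) — the standard definition, stated because summary reports
  often omit the formula.
- Series alignment is a nearest-timestamp join with a ±5 s default tolerance
  (half the nominal 10-s logging interval); unmatched ticks are dropped with
  a count, zero matches is an error. Co-location averages use the
  active-flame gravimetric window only, both ends inclusive.

## Problem sizes and determinism

The shipped tests and the acceptance script run entirely on generated data:
campaigns of 10–65 samples, 100–200 replicate campaigns for recovery and
coverage studies, and brute-force oracle comparisons at n ≤ 20 (where the
nested grid-search loops are cheap to enumerate exactly). These sizes give
Monte-Carlo standard errors small enough to detect coefficient biases of
order 0.01 while keeping the whole suite around a minute on one core. Every
stochastic routine requires an explicit seed, pipeline outputs are
byte-stable under a fixed seed (timestamps appear only in `run_info.txt`),
and CSV writers emit full-precision (`%.17g`) numerics so write/read round
trips are value-exact.

## Known limitations

- Knot estimation is intrinsically noisy: with a hinge of magnitude ~0.4 on
  the log scale, n = 65 and log-scale noise σ = 0.2, the knot estimate's
  spread is several tenths regardless of selection rule (CV or profile RSS).
  Expect the selected knot to wander by ±0.3–0.5 between replicate
  campaigns; only the noiseless case recovers it exactly.
- Back-transformed predictions are medians, not means (no smearing
  correction), so averages of adjusted series are mildly conservative under
  lognormal error.
- The published spline preset for humidity equation 1a with threshold ships
  its hinge coefficient exactly as printed (−4.051) although it is an order
  of magnitude away from its column neighbours; treat that single preset
  with suspicion and prefer refitting.
- Adjustment below ~600 µg/m³ nephelometric is extrapolation; the package
  warns rather than refuses.

## Session info

```{r}
sessionInfo()
```
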