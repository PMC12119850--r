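---
title: "Vacuum drying kinetics, diffusivity, thermodynamics and economics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vacuum drying kinetics, diffusivity, thermodynamics and economics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vacdry)
```

`vacdry` analyses thin-layer drying experiments on leafy herbs: one weighed
sample per run, dried at a fixed temperature and chamber pressure, with the
weight logged at regular intervals. This vignette explains the models the
package implements, the conventions and numerical choices behind them, what
the synthetic-data generator does and does not emulate, and the package's
known limitations.

## The data model

A run is a `drying_curve`: times in minutes starting at 0, sample weights in
grams and/or a dimensionless moisture-ratio trace, plus `drying_conditions`
(temperature in °C, gauge pressure in kPa with 0 = atmospheric, layer
thickness in metres, and wet-basis initial/equilibrium moisture fractions).
Moisture contents are carried **dry basis** internally (water per unit dry
matter, the basis on which the gravimetric definition and all kinetic models
operate); wet-basis values appear only at the I/O boundary, because that is
how practitioners report them. Time stays in minutes throughout the data
model; operations needing hours (drying rate) or seconds (diffusivity)
convert internally.

Negative interval losses caused by balance noise are deliberately retained
in the weight and rate series — raw data fidelity — and are filtered only
where mathematically necessary, i.e. points with MR ≤ 0 are dropped from
log-domain regressions and nowhere else.

The moisture ratio defaults to the simplified `MR = M_t / M_0`: for leafy
material the equilibrium moisture term is small relative to the initial
moisture, and this matches common thin-layer practice. The
equilibrium-corrected `MR = (M_t − M_e)/(M_0 − M_e)` is available via
`use_equilibrium = TRUE` whenever the conditions carry an equilibrium
moisture.

## Thin-layer model fitting

The bank holds nine classical closed forms (Page, Weibullian ×2, Midilli ×3,
logarithmic, Aghbashlo, Wang–Singh). Fitting minimises
`Σ (MR_obs − MR(t; θ))²` with the Levenberg–Marquardt algorithm
(`minpack.lm::nls.lm`). Choices worth knowing:

* **Initialisation.** The rate constant is seeded from the log-linear
  exponential fit (`fit_drying_constant`), shape exponents start at 1
  (the pure-exponential special case), amplitude terms at 1 and offsets at
  0. Up to four additional multiplicatively jittered restarts (seeded, 30%
  log-scale spread) run before a failure is declared; the best SSE wins.
* **Bounds.** Rate constants and Weibull scales are positive; exponents are
  confined to (0.05, 5); amplitudes to (0, 2); offsets are unbounded, and
  the Aghbashlo second constant may be negative (published estimates are).
  The box keeps curves physically decaying without excluding reported
  parameter values.
* **Inference.** Standard errors come from the Jacobian-based covariance
  `σ̂²(JᵀJ)⁻¹` with `σ̂² = SSE/(n−p)`; p-values are two-sided t tests on
  `n − p` degrees of freedom. A singular Jacobian leaves the SEs `NA` but
  still returns the fit. The goodness-of-fit statistics use the same
  convention: `RMSE = √(SSE/(n−p))`, and adjusted R² carries the
  `(n−1)/(n−p)` penalty, so adding a parameter at fixed SSE never improves
  it.
* **Ranking** is lexicographic: smallest RMSE, then largest adjusted R²,
  then fewest parameters. No information criteria are used.

The Page, Weibullian and base-10 Weibullian forms are the same curve under
`β = n`, `α = k^(−1/n)`, `δ = α (ln 10)^(1/n)`; `page_weibull_equivalents()`
does this exactly, and the tests require point-identical traces across the
three parameterisations.

## Diffusivity and activation energy

For an infinite slab dried from both faces, Fick's second law with uniform
initial moisture and equilibrated surfaces gives

`MR = (8/π²) Σ_{n odd} (1/n²) exp(−n² π² D_eff t / 4L²)`.

Two conventions matter:

* **L is the half thickness.** For a 1 cm layer, `L = 0.005` m. This is the
  standard both-faces slab convention and the only one under which the
  case-study drying constants reproduce the published diffusivities
  (0.0398 min⁻¹ → 6.72 × 10⁻⁹ m²/s). It is an explicit argument everywhere,
  never hard-coded.
* **Series indexing.** The sum runs over odd n with `n²` in both the weight
  and the exponent — the standard separation-of-variables solution, under
  which MR(0) → 1 as terms accumulate and the 50- vs 200-term difference is
  below 10⁻¹⁰ for dimensionless times ≥ 0.1. (Truncation at one term leaves
  the familiar log-linear form with intercept `ln(8/π²) ≈ −0.21`.) Note the
  t = 0 normalisation converges only at the slow 1/(4N) rate of the 1/n²
  tail: 200 terms reach 0.99899, not 0.9999.

`deff_from_curve()` regresses `ln MR` on time **with a free intercept**
(not forced through `ln(8/π²)`): a forced intercept would bias the slope
whenever the early drying deviates from the one-term regime. A non-negative
slope is returned flagged non-physical rather than silently erroring, so
grid-level pipelines can keep running. Temperatures convert as
K = °C + 273.15; the Arrhenius step is an OLS of `ln D_eff` on `1/T` with
`E_a = −slope·R`, `D_0 = exp(intercept)`. Activation energy is invariant to
rescaling all diffusivities — only `D_0` moves — which the tests assert.

## Transition-state thermodynamics

`eyring_fit()` implements the linearised Eyring equation
`ln(k/T) = ln(k_B/h) + ΔS‡/R − (ΔH‡/R)(1/T)` with
k_B = 1.38065 × 10⁻²³ J/K and h = 6.62608 × 10⁻³⁴ J·s. Because the intercept
— and therefore ΔS‡ — depends on the rate-constant unit, the unit is a
mandatory tag: the regression always runs on s⁻¹ (drying constants in min⁻¹
are divided by 60), and switching conventions shifts ΔS‡ by exactly
`R ln 60` ≈ 34 J/(mol·K).

Activation enthalpy is reported two ways. The Eyring slope gives a single
regression ΔH‡; the per-temperature convention `ΔH‡(T) = E_a − RT` gives the
temperature-dependent values (decreasing by R ≈ 0.0083 kJ/mol per kelvin)
that drying studies tabulate, and `thermo_summary()` uses the latter
together with the Eyring ΔS‡ and `ΔG‡ = ΔH‡ − TΔS‡`. A caveat worth
stating: published ΔS‡ magnitudes in this literature are often not
recoverable from the tabulated rate constants under either unit convention —
the package implements the equation faithfully and reports the unit tag
rather than guessing at an undocumented calibration; for the case-study
inputs only the sign pattern (ΔH‡ > 0, ΔS‡ < 0, ΔG‡ > 0: endothermic,
non-spontaneous, entropically unfavourable) is asserted.

## Economics

The scenario object carries the assumption set; every piece is exact
arithmetic. Conventions chosen where the source formulas were inconsistent:

* **Throughput.** Annual throughput is
  `(minutes_per_day / batch_time) × batch_mass × days_per_year` with
  fractional batches allowed; the default 600 effective drying minutes per
  day is the unique value reproducing the case study's nine published
  throughputs (e.g. 600/90 × 2 kg × 350 d = 4 666.7 kg/yr). It is a
  scenario field, not a constant. Likewise daily savings are
  `S_b × batches/day`.
* **Dried-product cost.** By default a flat `dried_cost` (4.25 USD/kg, the
  value implied by the case study's uniform 0.75 USD/kg savings across all
  conditions); supplying the fresh load mass instead activates the
  `C_dp = fresh_price × M_f/M_d` chain. Both behaviours are tested.
* **Payback.** The closed form
  `Ŧ = ln[1 − (C_cc/S_1)(d−i)] / ln((1+i)/(1+d))` is used as written. Its
  true d → i limit is `(1+d)·C_cc/S_1`; at exactly d = i the package falls
  back to the plain ratio `C_cc/S_1` with a method note (a deliberate,
  documented discontinuity of order d). A non-positive log argument raises
  a "never pays back" error.
* Currency is plain floating point; rounding to cents happens only in
  printed reports.

## The synthetic-data generator

`generator_spec()` fixes the emulated experiment: 100 g samples at 85.5%
wet-basis initial moisture drying towards 13.4% wb equilibrium (the midpoint
of the reported 13.1–13.7% range), 1 cm layers, 15-minute weighings, truth
kinetics Page with n = 1 and per-condition rate constants from the reported
3×3 grid (so the truth k is exactly the exponential drying constant), i.i.d.
Gaussian **weight-domain** noise with σ = 0.1 g (the balance accuracy), and
a stop rule of MR ≤ 0.01 or 510 min matching the reported 90–510 min span.
Noise lives in the weight domain because that is where a load cell errs; the
stored moisture-ratio trace is re-derived from the noisy weights through the
dry-matter mass balance, so measurement error propagates to every downstream
stage exactly as it would in a real experiment (the initial weighing is
anchored so MR(0) = 1).

What it does **not** emulate: drift or autocorrelation in the load cell,
temperature/humidity fluctuations inside the chamber, shrinkage or case
hardening of the leaves, non-Fickian early-stage transport, or
between-replicate biological variability. Passing recovery tests therefore
demonstrates correctness of the estimation chain under the stated noise
model, not robustness to every artefact of real dryers.

A propagation note that shaped the test design: the three study temperatures
span only 1.918 × 10⁻⁴ K⁻¹ in 1/T, so small relative errors in the three
rate constants amplify roughly four- to five-fold into the activation
energy. At σ = 0.1 g a single simulated grid recovers each k to ~1–2% but
E_a only to ~5%; unbiasedness is therefore verified on the mean over
replicate grids, while single-grid checks use correspondingly wider bands.

## Problem sizes and determinism

The test suite runs on desk-scale problems: curves of ≤ 35 points, 200-curve
Monte-Carlo recovery batches, ten-grid replication for the activation-energy
bias check, and a twice-refined 81×81 brute-force grid as the independent
optimisation oracle. All randomness flows through explicit integer seeds —
generator curves, jittered restarts, replicate indices — so every reported
number is reproducible from a seed, and re-running a pipeline with the same
inputs yields an identical report.

## Known limitations

* Only the slab geometry is implemented; cylindrical/spherical kernels and
  numerical solution of the radial diffusion PDE are out of scope, as is
  any psychrometric modelling of the drying air.
* The log-domain drying-constant and diffusivity regressions are unweighted,
  so near-equilibrium points (smallest MR) carry disproportionate relative
  noise; this mirrors standard practice but is statistically inefficient.
* No AIC/BIC model selection and no weighted nonlinear regression.
* Specific energy consumption is not modelled — the economics stop at the
  cost/savings/payback chain.
* The Eyring ΔS‡ depends on an arbitrary rate-constant unit convention;
  comparisons across studies require checking the tag.
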