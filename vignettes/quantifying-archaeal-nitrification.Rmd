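---
title: "Quantifying archaea-driven nitrification from single cells to ecosystem fluxes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying archaea-driven nitrification from single cells to ecosystem fluxes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aoaflux)
```

## The quantification problem

Deep oligotrophic lakes sustain large hypolimnetic populations of
ammonia-oxidizing archaea (AOA), which convert ammonia to nitrite — the
rate-limiting first step of nitrification. Linking those populations to an
ecosystem-level nitrogen flux requires chaining together measurements made
at very different scales:

1. **bulk rates** — ¹⁵N-ammonium tracer incubations in which the
   appearance of ¹⁵N in nitrite + nitrate (¹⁵NOₓ) over ~48 h gives a
   potential ammonia oxidation rate in nmol l⁻¹ d⁻¹;
2. **population size** — a qPCR time series of archaeal *amoA* gene
   copies (a single-copy gene, so copies ≈ cells) in copies ml⁻¹;
3. **single cells** — nanoSIMS ion counts over CARD-FISH-identified cells,
   giving per-cell ¹⁵N atom fractions, growth and N-assimilation rates,
   and cell dimensions;
4. **the ecosystem** — integration of cell-specific rates over the
   seasonal abundance cycle and the hypolimnion volume, compared against
   phytoplankton production and the lake's nitrate budget.

`aoaflux` implements this cascade as composable functions with a shared
uncertainty-carrying scalar type, plus a synthetic-data generator that
emulates the statistical structure of each input so the entire pipeline is
testable without the field data.

## The model and its assumptions

### Bulk rates: OLS on tracer time series

`potential_rate()` is the package's fitting function. For one incubation
bottle it regresses ¹⁵NOₓ concentration on time (ordinary least squares via
`stats::lm`); the slope is the potential rate. A rate is only reported when
the slope is significantly greater than zero by a one-tailed t-test with
n − 2 degrees of freedom at p < 0.05; `replicate_rate()` averages the
significant bottles of a triplicate and reports the between-bottle standard
deviation as the spread. Assumptions: label production is linear over the
incubation (empirically R² = 0.91–1.00 in the motivating system), bottles
are exchangeable, and residuals are approximately Gaussian.

Two modelling choices were genuinely open and are resolved as follows.
*Per-bottle fits, then averaging* (rather than pooling all bottles into one
regression) matches a design with n = 3 biological replicates and yields a
replicate spread directly. *The t = 0 sample is a regression point*: it is
taken immediately after isotope addition and carries the same measurement
error as later points, so excluding it would discard information. Rates are
**not** corrected for the labeling fraction — `labeling_fraction(10, 0.07)`
exceeds 0.99, so the correction is below 1% — but
`correct_labeling = TRUE` applies it for sensitivity analysis, and can only
increase the rate.

### Per-cell carbon: geometry and allometry

Cells are modelled as prolate spheroids, `V = π/6 · W²L`
(`prolate_volume()`), and volume maps to carbon through the empirical
cross-species allometry `m_C = 197 · V^0.46` fg C (`carbon_content()`).
Averaging order matters because both maps are nonlinear:
`summarize_cell_geometry()` computes per-cell volumes and carbon **first**
and then averages, which is the faithful treatment of a measured cell
population; the volume of the average cell (0.043 µm³ for a 0.39 × 0.54 µm
cell) is systematically *below* the average of per-cell volumes
(≈0.048 µm³ at the observed dimension spread) — a Jensen-gap direction the
test suite asserts on simulated populations. The per-cell carbon of the
mean-dimension cell, 46 fg C, is the value carried into standing-stock
calculations, where `volumetric_carbon()` multiplies it by the *amoA*
abundance (one copy = one cell; no qPCR-efficiency correction is applied,
matching the convention of using copy numbers as reported).

### Single cells: enrichment to rates

`atom_fraction()` is the standard isotope-ratio definition
c¹⁵/(c¹⁵ + c¹⁴) on the ¹²C¹⁵N⁻/¹²C¹⁴N⁻ ion counts. `growth_rate()`
implements the linear tracer-uptake form

µ = (x_meas − x_nat) / ((x_label − x_nat) · t)

with the natural-abundance baseline fixed at 0.003663 (atmospheric N₂). A
compound-interest variant, µ = ln(1 + excess/(x_label − x_meas))/t, is
available behind `method = "compound"`; the two agree to better than 1% at
the small enrichments of environmental cells. `assimilation_rate()`
multiplies µ by a cellular N quota. The quota default of 420 amol N cell⁻¹
is the value jointly consistent with mean observed growth (0.012 d⁻¹) and
assimilation (5.04 amol cell⁻¹ d⁻¹) rates in the motivating system; note it
is *not* the Redfield-C:N quota implied by 46 fg C (~580 amol), so the
quota is an explicit, configurable parameter rather than a derived one —
`n_quota_from_carbon()` derives alternatives from carbon and any C:N mass
ratio. No correction is applied for isotope dilution introduced by
CARD-FISH; all single-cell rates are therefore conservative lower bounds,
and the tests assert that enabling any positive dilution factor can only
raise them.

The target vs. non-target enrichment contrast (`enrichment_contrast()`) is
a Mann–Whitney U test, one-sided by default (the directional hypothesis is
that target cells are more enriched). For min(n₁, n₂) ≤ 8 the p-value is
computed by exact enumeration of all C(n₁+n₂, n₁) group assignments of the
pooled values — valid under ties, where the classical exact distribution is
not — and otherwise by the tie-corrected normal approximation. Unit tests
cross-check both paths against `stats::wilcox.test` and against a
brute-force permutation oracle.

### Ecosystem scaling

`annual_rate()` implements the time integral of cell-specific rate ×
abundance: the trapezoidal time-weighted mean abundance (exact for
piecewise-linear dynamics, and verified against a refined daily Riemann
oracle to <0.5%) times the mean cell-specific rate, expressed per year.
All time arithmetic uses a 365-day year; this keeps the closed form for a
constant series (r_cell × A × 365 d) and the unit conversion
1 nmol l⁻¹ d⁻¹ = 14 × 365 × 10⁻³ = 5.11 mg N m⁻³ y⁻¹ mutually consistent.
The nitrogen *mass* basis (molar mass 14) is used throughout and outputs
are labelled NH₄⁺-N: this is the convention under which the volumetric and
whole-lake flux figures are arithmetically coherent, whereas an NH₄⁺ mass
basis (18 g mol⁻¹) would not be.

`lake_total()` scales by the hypolimnion volume; `budget_fractions()`
expresses the flux against phytoplankton N production and the annual
nitrate-pool input. The Redfield ratio is applied **as a mass ratio**
(16/106) by default in `phytoplankton_nitrogen()` — the convention under
which productivity × area × 16/106 reproduces the budget this package
targets — with the molar-correct variant (16·14/106·12, ~17% higher)
available as `mode = "molar"`. Percentages are presentation-rounded to
integers only in reports.

### Uncertainty propagation

Every derived quantity is a `uv` (value ± standard uncertainty). Sums
combine uncertainties in absolute quadrature, products and ratios in
relative quadrature — the ratio rule reproduces the ±0.06 and ±0.08
spreads of the two measured cell-specific rates exactly. `uv_mean()`
offers two spreads for a mean of measurements: quadrature of the input
uncertainties over n (how well the mean is known) and the sample SD of the
values (how variable the measurements are). Neither mode reproduces the
±0.9 and ±0.11 quoted alongside the 6.0 nmol l⁻¹ d⁻¹ and
0.21 fmol cell⁻¹ d⁻¹ means in the motivating study — quadrature/n gives
±0.23 and ±0.05, sample SD ±1.29 and ±0.017 — so both are documented here
rather than silently matched; the discrepancy does not affect the central
values.

## What the synthetic data emulate — and what they do not

`scenario_config()` fixes the simulated study conditions; generators are
pure functions of (configuration, seed):

* **Abundance** (`gen_abundance_series()`): an annual sinusoid between a
  winter minimum of 9.8 × 10³ and a summer maximum of 1.2 × 10⁵ copies
  ml⁻¹ (peak near day 200), observed with multiplicative lognormal qPCR
  noise at 30% CV across 3 replicates. The sinusoid is a chosen functional
  form — the real dynamics show winter minima and summer maxima but no
  stated shape; lognormal noise is the standard error model for qPCR, with
  the CV set from the reported replicate spreads (~25–40%).
* **Tracer kinetics** (`gen_tracer_incubation()`): ¹⁵NOₓ linear at
  6.0 nmol l⁻¹ d⁻¹ with Gaussian σ = 0.3 nmol l⁻¹ per measurement,
  sampled at 0/12/24/48 h in triplicate, clipped at zero.
* **Single cells** (`gen_single_cells()`): 37 target cells with
  truncated-normal atom-fraction excess (mean 0.0239, SD 0.0119 — the
  excess corresponding to µ = 0.012 d⁻¹ over 2 d at 99.3% labeling)
  against 105 non-target cells jittered narrowly around natural abundance;
  dimensions truncated-normal at 0.54 ± 0.11 × 0.39 ± 0.10 µm; fractions
  discretised into counts at 2 × 10⁵ total ions per ROI.

These generators reproduce the *statistical structure* the estimators
assume — linearity, noise families, group sizes, seasonal range. They do
not emulate real-data complications: non-sinusoidal bloom dynamics,
temporally correlated qPCR error, nanoSIMS deadtime/drift, CARD-FISH
isotope dilution, or depth structure. Passing tests therefore demonstrate
correctness of the estimators under their stated assumptions, not
robustness to violations of them.

## Numerical choices and degenerate inputs

* An exactly collinear tracer series has zero residual variance; its
  p-value is set to the smallest representable double rather than 0, and a
  flat series gets slope 0 with p = 1.
* Residuals below 10⁻¹⁰ of the data scale are treated as exact
  collinearity to keep floating-point dust from fabricating t-statistics.
* Negative simulated concentrations are clipped at zero (concentrations
  are physical); the type-I error simulation shows the significance filter
  stays at or below its nominal 5% under this clipping.
* Cell geometry enforces width ≤ length by swapping on construction.
* Dates integrate on the calendar-day scale; the span is converted to
  years at 365 d.
* Exact Mann–Whitney enumeration is limited to min(n₁, n₂) ≤ 8 (at most
  C(16, 8) = 12 870 assignments), beyond which the normal approximation's
  error is negligible.
* Measurements with unknown uncertainty (`sd = NA`) propagate as exact and
  print without a ± term.

## Problem sizes used in the test suite

Property-style checks run at deliberately small, fixed sizes chosen to make
their Monte-Carlo error much smaller than the asserted tolerances: 10⁴
null simulations for the type-I error bound, 10³ replicates for estimator
bias and confidence-interval coverage, 25–60 random instances for the
closed-form and permutation oracles, and populations of 500–2000 simulated
cells for the Jensen-gap direction. All random tests fix their seeds.

## Worked example

```{r example, eval = FALSE}
library(aoaflux)

# per-cell carbon from the mean observed cell dimensions
m_c <- carbon_content(prolate_volume(0.39, 0.54)) # 46.3 fg C

# carbon standing stock at the mean abundance
volumetric_carbon(signif(m_c, 2), 4.3e4) # 2.0 mg C m-3

# measured-rate table -> cell-specific rates -> annual flux
r_jun <- cell_specific_rate(uv(5.67, 0.38), uv(2.50e4, 0.63e4))
r_nov <- cell_specific_rate(uv(7.72, 0.66), uv(3.81e4, 1.55e4))
r_cell <- uv_mean(c(r_jun, r_nov)) # 0.21 fmol cell-1 d-1

s <- abundance_series(c("2017-11-21", "2019-11-05"), c(4.3e4, 4.3e4))
r_annual <- annual_rate(s, round(uv_value(r_cell), 2)) # 46.1 mg N m-3 y-1
lake_total(r_annual)$tons_n_per_y                      # ~1760 t N y-1
budget_fractions(lake_total(r_annual)$g_n_per_y)       # 11% / 4%
```

## Known limitations

* Rates come from one depth and one temperature; no depth-resolved or
  temperature-corrected (Q₁₀) modelling is attempted.
* Potential rates (measured after 10 µM substrate amendment) are upper
  bounds on in-situ rates; the ecosystem flux is correspondingly a maximum
  capacity.
* The uncertainty calculus is first-order Gaussian propagation; it ignores
  correlation between numerator and denominator in ratios (rates and
  abundances are measured independently, so this is mild) and is
  inaccurate for relative errors approaching 1.
* The cellular N quota is a parameter, not an observable; headline
  assimilation rates scale linearly with it.
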