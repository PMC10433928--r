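---
title: "Methods: trait-based analysis of stomatal regulation of sap flux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: trait-based analysis of stomatal regulation of sap flux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hydrotraits)
```

## The scientific problem

As air dries (vapour pressure deficit *D* rises), trees first transpire more,
then stomata intervene: sap flux density *J~s~* saturates or declines. Where
that turnover happens, and how strongly conductance is cut back, differs
among species and is thought to be set by hydraulic traits — above all the
Huber value *H~v~*, the sapwood area invested per unit leaf area. This
package implements the full analysis chain for such a study: per-tree
response curves, anatomical and functional trait computation, calibration of
a mechanistic conductance model, and the cross-species statistical layer.

## Response curves

Morning (dawn-to-noon) *J~s~*–*D* data, pooled over the measurement days,
are fitted per tree with two forms:

* **Parabolic** *J~s~* = a·D² + b·D, fitted *without intercept*: physically,
  flux vanishes with the deficit, and the printed form of the model has no
  constant. An optional intercept flag exists but defaults off. The vertex
  is extracted analytically (D~Jsmax~ = −b/2a; J~smax~ by substitution).
  When the fitted curvature is non-negative there is no interior maximum:
  the vertex fields are `NA` with status `"no_vertex"` and a warning, never
  silent `NaN`.
* **Logarithmic** *J~s~* = J~sref~ + m~Js~·ln D by ordinary least squares;
  m~Js~ is the drought sensitivity, J~sref~ the flux at D = 1 kPa.

Because the parabolic model has no intercept, its R² is computed against the
mean-of-flux baseline (1 − RSS/TSS~mean~) so the two models are comparable;
it can be negative. Model selection takes the higher R², with ties going to
the parabolic form (the adopted extraction model). Both fits require at
least three points and reject rank-deficient designs (all deficits equal).

**The morning window.** Afternoon data trace a hysteresis loop (stored water,
radiation lag), so fitting uses dawn-to-midday rows only. "Dawn" is defined
operationally as the day's first deficit reading above 0.1 kPa and "midday"
as 12:00 solar time, inclusive; a day whose deficit never clears the
threshold raises an error naming the day. This rule is a package convention:
the field protocol it encodes says only "dawn to mid-day".

## The mechanistic conductance model

For canopies tightly coupled to the atmosphere, inverting the simplified
Penman–Monteith equation gives g~s~ = λγE/(ρ~air~C~p~D). Treating the four
meteorological factors as constant over a campaign day collapses them into
C = λγ/(ρ~air~C~p~), evaluated by default at 20 °C and 101.3 kPa with
λ = (2.501 − 2.361×10⁻³ T)×10⁶ J kg⁻¹, γ = C~p~P/(0.622λ), dry-air density
from the ideal-gas law, and C~p~ = 1013 J kg⁻¹ K⁻¹. Substituting
E = H~v~·J~s~ yields g~s~ = C·H~v~·J~s~/D. Since field units are mixed
(J~s~ in cm h⁻¹, D in kPa, g~s~ in mol m⁻² s⁻¹), `mechanistic_constant()`
also returns the fully unit-harmonised factor (water density for the
volumetric-to-mass conversion, cm h⁻¹ → m s⁻¹, division by the molar volume
of air), with the algebra recorded in an audit trail. Calibration
(`calibrate_gs()`) regresses measured g~s~ on J~s~/D per tree; the default
includes an intercept — field calibrations are empirical and an intercept
absorbs baseline offsets — while `intercept = FALSE` gives the strict
proportional form of the model. Conductance spot readings are paired to the
half-hourly flux by nearest timestamp within ±15 min; unmatched readings are
dropped with a message. Two-sided t-tests on the slope at α = 0.05 decide
which trees enter the cross-tree slope-vs-H~v~ regression.

## Traits

* **Theoretical maximum stomatal conductance.** The anatomical upper bound is
  computed with the canonical diffusion form
  g~smax~ = d·n·a~max~ / (v·(p~d~ + (π/2)·√(a~max~/π))), with diffusivity
  d and molar volume v as configuration (defaults 2.49×10⁻⁵ m² s⁻¹ and
  0.0245 m³ mol⁻¹ at 25 °C), stomatal density n on the abaxial side only
  (an amphistomatous flag doubles the flux), and pore depth p~d~ derived
  from stomatal size S as half the guard-cell width under a 2:1
  length:width outline, p~d~ = √(S/2)/2. The algebraic arrangement is a
  *swappable function argument*: published forms of this expression vary
  and some printings are not dimensionally parseable, so the package never
  hard-codes one silently — alternatives can be passed and compared.
* **Hagen–Poiseuille conductivity** k~s~ = (πρ/128ηA)·Σd⁴ with water
  density and viscosity fixed at their 20 °C values (998.2 kg m⁻³,
  1.002×10⁻⁹ MPa s). The d⁴ law is checked by an exact splitting property
  (two vessels of half diameter carry 1/8 the conductivity).
* **Plant hydraulic conductance** K~plant~ = g~s~·D/(Ψ~pd~ − Ψ~min~). The
  field convention mixes units: D enters numerically in kPa and the
  potential difference in MPa, giving K~plant~ in mol m⁻² s⁻¹ MPa⁻¹. The
  package documents (rather than "fixes") this convention, and the
  simulator inverts exactly the same expression, so recovery is exact.
* **Huber value** via branch allometry: leaf area is predicted from branch
  diameter with an OLS power law on the log-log scale; predictions outside
  the fitted diameter range are allowed but always flagged as
  extrapolations, mirroring field practice.
* **Derived ratios**: conductance reduction at D~Jsmax~ (evaluated from a
  per-tree log-linear g~s~–ln D fit; values above 1 from sampling noise are
  clipped to 1 with a warning) and J~smax~/g~smax~, the functional analogue
  of H~v~. Measured g~smax~ is the mean over measurement days of the tree's
  daily maximum.

## Cross-species statistics

* **PCA** standardises each trait and eigendecomposes the correlation
  matrix; the sign convention (largest-magnitude loading positive, ties by
  trait order) makes loadings deterministic. Missing cells and constant
  columns are errors, the latter naming the trait.
* **LMG relative importance** decomposes a regression's R² by averaging each
  regressor's incremental R² over all p! entry orderings (the Shapley value
  of the R² game). It is implemented from first principles by exact
  enumeration — R² of all 2^p subsets plus factorial weights, identical to
  the literal ordering average — and is restricted to p ≤ 8. Confidence
  intervals come from a case-resampling bootstrap (default 1000 runs,
  percentile intervals); resamples with fewer than p + 2 distinct rows are
  redrawn and counted. Shares sum to the model R² by a telescoping
  identity, which the tests assert to 10⁻¹⁰.
* **Tukey comparisons** use the studentized-range distribution via base R's
  numerical integration (`ptukey`), with the Tukey–Kramer standard error
  for unequal group sizes; at two groups this reduces analytically to the
  pooled t-test, which is asserted to 10⁻⁶. Optional log or square-root
  pre-transformations are applied before fitting and recorded in the
  output. The compact letter display uses insert-and-absorb: start from one
  class holding all groups, split on each significant pair, absorb subset
  classes, ties broken by group order.
* **Calibration-quality model**: per-tree calibration R² regressed on H~v~
  and K~plant~ across all species pooled, with residual diagnostics
  (Shapiro–Wilk, Breusch–Pagan, design condition number) and LMG shares
  with bootstrap intervals. With fewer than six trees the model is refused.
  A response with no variance (as in a noise-free campaign, where every
  calibration is perfect) has no R² to decompose; the shares are reported
  as `NA` with a warning instead of failing the stage.

## The synthetic campaign

Field datasets of this kind are rarely public, so the simulator is a
first-class module: every estimator in the package is validated by
parameter recovery against its ground truth.

**What it emulates.** Five orchard-species presets (almond, olive, orange,
grapefruit, lemon) spanning the observed ranges: H~v~ 1–3.8×10⁻³ cm² cm⁻²,
maximum conductance 0.11–0.27 mol m⁻² s⁻¹, deficit-at-maximum-flux
2.9–4.9 kPa, plant conductance 1.25–5.04 mol m⁻² s⁻¹ MPa⁻¹, vein density
5.5–11.5 mm mm⁻². Where species values are published (almond, olive, lemon)
the presets use them; orange and grapefruit are set as citrus intermediates.
Per species, the conductance-decline parameters are back-solved once from
the target deficit-at-maximum-flux via the closed form D\* = exp(g~sref~/m − 1)
and the target maximum conductance at 0.1 kPa. The campaign design mirrors
the emulated protocol: three measurement days, 30-min cadence, four
instrumented trees per species, deficit ramping 0.1–4.5 kPa as a truncated
sine from dawn to solar noon (identical across days — day-to-day weather
variation adds nothing to the recovery logic and would shrink the fitted
deficit range on some days). Air temperature tracks the ramp (18–35 °C),
leaf temperature runs up to 1 °C warmer at midday, and relative humidity is
back-solved so that recomputing the deficit from the stored leaf/air
temperatures and humidity reproduces it to 10⁻⁹ kPa (Tetens saturation
formula throughout; the emulated protocol names none, and Tetens is the
standard agrometeorological choice).

The forward model is the conductance model run in reverse: true conductance
declines log-linearly, g~s~ = max(0, g~sref~ − m·ln D), floored at zero, and
flux is J~s~ = g~s~·D/(C~full~·H~v~) plus additive Gaussian noise
(σ~Js~ = 0.25 cm h⁻¹ by default, about 5 % of the flux maximum). Measured
conductance carries its own Gaussian error (σ~gs~ = 0.02 mol m⁻² s⁻¹, an
IRGA-scale repeatability) and is floored at zero. Water-potential pairs
invert the plant-conductance definition with pre-dawn potentials drawn from
a well-watered −0.5 to −0.3 MPa. Anatomy tables use lognormal vessel
diameters on fixed 1.5 mm² transects, stomatal counts and sizes with 5 %
lognormal sampling error, branch allometry pairs with 8 % log-scale leaf-area
noise over the 6.2–20 mm diameter range, and vein densities on 10 mm²
leaf regions.

**Tree-level coordination.** Trees vary around their species preset: Huber
value and plant conductance are lognormal with SD 0.25, a two-to-threefold
within-species spread typical of allometry-derived Huber values. Critically,
each tree's conductance curve (g~sref~ and m jointly, which preserves the
species' hump position) scales with its Huber value. This encodes the
coordination the model itself describes — conductance tracks
leaf-area-specific hydraulic supply — and it is what makes calibration
quality H~v~-driven at the tree level: without it, a high-H~v~ tree would
merely have a noisier J~s~/D regressor and a *worse* calibration, inverting
the structure the system is known to show. Plant-conductance variation stays
independent of H~v~ (measurement plus soil–root variation), so it carries no
such signal.

**What it does not emulate.** No radiation or boundary-layer control of
transpiration (canopies are treated as fully coupled), no soil water
deficit, no stem capacitance or g~s~–J~s~ time lags, no heat-pulse probe
physics, and no afternoon hysteresis beyond what the morning window would
discard anyway. One consequence of strict internal consistency deserves
note: with conductance and Huber values at realistic magnitudes, the
simulated flux maxima are of order 5 cm h⁻¹, an order below typical field
heat-pulse readings — real point measurements embed probe-placement and
sapwood-integration factors that an empirical calibration absorbs but a
strictly inverted model does not. Recovery tests are therefore exact in
structure but not a statement about field flux magnitudes; passing them
shows the estimators are correct, not that real data are this clean.

## Numerical choices and degenerate inputs

Analytic identities (parabola vertex, LMG share sum, splitting law) are
asserted to 10⁻¹²; OLS results against normal-equation oracles to 10⁻¹⁰;
recovery of the closed-form flux hump to 10 % under the default noise.
Zero-variance regressors, empty vessel lists, non-positive areas, inverted
water-potential gradients, and single-value groups are all explicit errors;
conductance reductions marginally above 1 are clipped with a warning rather
than propagated. Seeds: one integer seed fixes a whole campaign
byte-for-byte; the bootstrap and the pipeline derive their determinism from
the same configuration.

Problem sizes used in the shipped tests and the acceptance script — 5
species × 4 trees × 3 days at 30-min cadence, 1000-rep null simulations,
1000 bootstrap resamples, 50-seed stability checks — were chosen as the
smallest sizes at which the Monte-Carlo assertions have comfortable margins;
they match the emulated campaign's own dimensions.

## Known limitations

The calibration's significance filter assumes independent errors;
autocorrelated half-hourly flux would make its p-values optimistic. The
theoretical-conductance formula arrangement is a convention (hence
swappable). The K~plant~ unit convention follows field practice rather than
dimensional purity. And all headline structure recovered from the simulator
is, by construction, structure the simulator contains; the package
demonstrates estimator correctness and pipeline integrity, not new field
inference.
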