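---
title: "Methods: inflammation-adjusted serum zinc and geostatistical mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inflammation-adjusted serum zinc and geostatistical mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the statistical machinery in `znspatial`: what each
stage assumes, which tunable parameters matter, why the defaults are what
they are, and what the synthetic-data generator does and does not emulate.

## The analysis problem

National micronutrient surveys measure serum zinc in a cluster sample:
participants are recruited within enumeration areas (EAs), the
census-defined geographic clusters. Three features complicate a naive
prevalence estimate:

1. **Inflammation.** Serum Zn falls during the acute-phase response, so
   inflamed participants look more deficient than they are. The
   concentrations of C-reactive protein (CRP, mg/L) and
   alpha-1-acid-glycoprotein (AGP, g/L) index the severity and duration of
   inflammation and can be used to correct the biomarker.
2. **Draw context.** Serum Zn varies with time of day and fasting status,
   so deficiency cutoffs are specific to age band, sex, morning/afternoon
   draw, and fasting.
3. **Spatial dependence.** Zn status reflects local food systems and soils;
   quantifying its spatial correlation supports mapping and survey design,
   and requires distances computed on the sphere for a country-scale
   survey.

The pipeline is: exclusion cascade, inflammation staging, BRINDA
adjustment, cutoff classification and weighted prevalence, EA aggregation,
robust variogram estimation, weighted-least-squares exponential model
fitting, cross-validated model selection, ordinary kriging, and
threshold-exceedance mapping.

## Exclusion cascade and staging

Records are dropped in a fixed order — missing GPS, missing meal/draw time
(either draw time or fasting status absent), missing CRP or AGP, missing
socio-demographics, analytical outlier flag — and each exclusion is
attributed to the *first* matching reason. This makes the reported counts a
partition of the excluded set, which is the property the tests enforce
(`n_input = sum(reasons) + n_retained`).

Inflammation staging uses the standard four-way classification with
thresholds CRP 5 mg/L and AGP 1 g/L: none (both at or below), incubation
(CRP elevated only), early convalescence (both elevated), late
convalescence (AGP elevated only). The boundary case "CRP elevated, AGP
exactly 1" is assigned to incubation: the no-inflammation cell is defined
by `<=` on both markers, so keeping `<=` for the AGP side of incubation
makes the partition exhaustive without overlap.

## BRINDA internal regression correction

The correction regresses `ln Zn` on `ln CRP` and `ln AGP` by OLS over the
analysis cohort (a single national fit, not per-group fits), then deflates
each record's log markers by their reference values:

```
Zn_adj = exp[ ln Zn − beta1 (ln CRP − ref_CRP)+ − beta2 (ln AGP − ref_AGP)+ ]
```

where each term is applied only when that marker's log value exceeds its
reference (term-wise), and the reference is the maximum of the lowest
decile of the log marker over the same cohort. Consequences worth knowing:

* The adjustment is the identity for records with both markers at or below
  the references, and with negative fitted slopes it can only raise Zn —
  both are tested invariants.
* Because the decile references sit well below the clinical cutoffs (5
  mg/L and 1 g/L), most records receive *some* adjustment, including many
  staged "no inflammation". This is a property of the method, preserved
  deliberately.
* Markers at or below zero (below assay detection) are shifted by half the
  smallest positive observed value before logging; configurable. Dropping
  them would change the cohort, which seemed worse than a documented
  shift.
* Slopes are applied with their estimated signs; adjusted values are not
  truncated.

The reference is computed as the largest observation among the lowest 10%
of values (`sort(x)[floor(0.1 n)]`), i.e. an observed value, not an
interpolated quantile.

## Deficiency classification and prevalence

The cutoff table (µg/dL, strict `<`) ships as CSV and covers: children
under 10 (65 morning / 57 afternoon, non-fasting, either sex), and
participants 10 and older (morning non-fasting 70 male / 66 female;
afternoon non-fasting 61 male / 59 female; morning fasting 74 male / 70
female). Age exactly 10 uses the older band. Combinations outside the
table (afternoon fasting, fasting children) raise an explicit "no cutoff
defined" error; silently defaulting would misclassify. Prevalence is the
weighted share of deficient records per stratum; it is invariant to
rescaling the weights, and no design-based standard errors are attempted
(point prevalence only). The sampling-weight column is taken as given.

Weighted medians use the midpoint-CDF convention with linear
interpolation, chosen because it reduces exactly to the ordinary median
under equal weights for both odd and even n.

Rank correlations (Spearman, average ranks for ties) are computed
unweighted on pairwise-complete observations; whether a survey-weighted
version is preferable is left open, and the unweighted choice is
documented at the function.

## Spatial support and distances

Spatial analysis uses the demographic group with the widest EA coverage
(women of reproductive age by default). Records are averaged, unweighted,
to EA means of adjusted Zn and EA mean coordinates — the variogram then
describes between-EA variation on that support. A sanity check warns if
one EA's records spread more than 25 km around their centroid.

All lags are great-circle distances on a sphere of radius 6371.0088 km
(haversine; the tests cross-check against an independent spherical
Vincenty implementation). No map projection is used: at country scale no
single plane projection preserves distances adequately. Bearings for the
directional variogram are final bearings at the second point, folded
modulo 180°, with four 45° sectors centred on 0/45/90/135°. Anisotropy is
assessed by overlaying the sector variograms; no formal test is applied.

Before variogram estimation, EA means outside Tukey's outer fences (hinges
± 3 × hinge spread, via `fivenum()`) are flagged as probable outliers and
withheld — extreme values inflate semivariance estimates — but they are
reinstated for kriging prediction, where a genuine (if unusual)
observation should still inform the local estimate.

## Variogram estimation and model fitting

Three binned estimators are provided, all over pair differences
`d = z_i − z_j` within half-open lag bins `[lower, upper)` (default 10-km
bins to 200 km; the bin spec is a configurable design choice, not a claim
about any particular published figure):

* Matheron (method of moments): `sum(d²) / 2N` — efficient under
  Gaussianity, sensitive to outliers;
* Cressie–Hawkins: fourth power of the mean root absolute difference,
  bias-corrected by `2(0.457 + 0.494/N)`;
* Dowd: `2.198 median(|d|)² / 2` — robust to spatial outliers.

On the sphere not every planar variogram family remains valid; the
exponential model `gamma(h) = c0 + c1 (1 − exp(−h/a))` is, and is the only
family fitted. `c0` (nugget) absorbs measurement/analytical error and
variation at scales finer than the sampling scheme — including, on the EA
support, the within-EA sampling variance of the EA means; `c1` is the
spatially correlated variance; the effective range is approximately `3a`.

Fitting is weighted least squares with Cressie's weights `N_j /
gamma(h_j; theta)²`, iteratively reweighted (plain `N_j` weighting is
available). The objective is minimised by bounded quasi-Newton (L-BFGS-B)
on `(c0, c1, ln a)` with non-negativity constraints and a multistart grid
`a ∈ {5, 10, 20, 40, 80}` km; ties break to the lowest objective, then the
smallest `a`. A noise-free round trip (bin values generated from a known
model) recovers parameters to relative error below 1e-4 in the tests. A
flat empirical variogram collapses `c1` to zero with a pure-nugget
warning rather than failing.

## Ordinary kriging and its conventions

Kriging solves the semivariance-form system with the unbiasedness
constraint; weights sum to one (tested to 1e-10). Two conventions matter:

* **Exact interpolation:** `gamma(0) = 0` at a coincident target/datum, so
  predictions at data sites return the datum with zero variance. The
  nugget is treated as micro-scale-plus-measurement variance attached to
  point observations. This also makes leave-one-out cross-validation well
  posed.
* **Global neighbourhood by default:** a few hundred EAs is tractable
  directly; a nearest-k option exists for larger inputs. Duplicate data
  locations are an error, never silently jittered.

Far beyond the range of all data the prediction tends to the
generalised-least-squares mean of the observations and the kriging
variance exceeds the total sill — both are tested against closed forms.

## Cross-validation, SSPE, and model selection

Each EA is removed in turn and predicted from the rest; the squared error
is standardised by the leave-one-out kriging variance. Under a valid model
with Gaussian errors each standardised squared error is chi-square with
1 df, so the *median* SSPE has expected value 0.455 — robust to the heavy
right tail of the squared errors. A median inside the published validity
interval (0.355, 0.575) is taken as consistent with a valid model; the
interval is used as a fixed criterion, not recomputed per n (an
order-statistic interval utility is provided for diagnostics only).

The leave-one-out loop is computed through the inverse of the bordered
kriging matrix (error `(Hz)_i / H_ii`, variance `−1/H_ii`), which is
algebraically identical to removing each site and re-solving; the test
suite verifies this equality against the explicit refit loop. This makes
calibration experiments with hundreds of replicates cheap.

Selection logic: the Matheron estimator is the most statistically
efficient, so its fitted model is accepted outright when its median SSPE
is valid; only otherwise are the robust-estimator fits cross-validated,
and the model with median SSPE closest to 0.455 is chosen. If nothing is
valid the closest model is returned flagged invalid — never silently
accepted. The decision trail is recorded.

## Exceedance probability and calibrated phrases

The ordinary kriging prediction distribution is taken as Gaussian, so the
probability that Zn falls below a threshold t is
`Phi((t − prediction)/sigma_K)`, degenerating to 0/1 by direct comparison
when the kriging variance is zero. The default threshold is 70 µg/dL.
Probabilities are labelled with the IPCC calibrated likelihood language
(virtually certain [0.99, 1], very likely [0.90, 0.99), likely
[0.66, 0.90), about as likely as not [0.33, 0.66), unlikely [0.10, 0.33),
very unlikely [0.01, 0.10), exceptionally unlikely [0, 0.01)); the bins
follow the IPCC source and partition [0, 1].

A national 60-m grid would have on the order of 10^9 nodes and is not
desk-feasible; the default grid resolution is 0.1–0.25° with a configurable
node cap of 10^6.

## What the synthetic generator emulates

The generator exists so that every stage has a testable input with known
ground truth; the restricted survey data are not required anywhere.
Defaults, chosen once to represent a realistic national survey of this
kind:

* 343 EAs uniform over a 33–48°E × 3.5–14.5°N window; 9–11 participants
  per EA; demographic mix YC 16.9%, SAC 31.4%, men 13.1%, WRA 38.6%.
* A latent EA-level Gaussian Zn field with mean 60 µg/dL and exponential
  variogram (nugget 27.0, partial sill 39.62 (µg/dL)², distance parameter
  14.79 km): the smooth component lives at EA centroids, the nugget is
  independent noise per value, matching the kriging exactness convention.
* Log-normal markers: `ln CRP ~ N(−0.11, 1.4)` and
  `ln AGP ~ N(−0.262, 0.45)`, correlated 0.416 on the log scale via a
  Gaussian copula. These put ~11% of participants above CRP 5 mg/L, ~28%
  above AGP 1 g/L, and the marker–marker rank correlation near 0.40.
* Individual `ln Zn = ln(EA value) + beta_crp (ln CRP − mu) + beta_agp
  (ln AGP − mu) + noise`, with defaults `beta_crp = −0.01`,
  `beta_agp = −0.07` and within-EA log-noise sd 0.25 (exposed as a config
  knob; surveys do not report this quantity directly). Together these
  target a Zn–AGP rank correlation near −0.14 while keeping a realistic
  within-EA coefficient of variation (~25%).
* Missingness is injected per field at configurable rates; the seed is
  mandatory and fixed-seed runs are byte-identical.

The analytic deficiency probability under this model (a one-dimensional
quadrature over the EA field) serves as the oracle for prevalence tests.

What it does **not** emulate: real administrative geography or
population-proportional EA selection; informative sampling weights
(weights are drawn independently of Zn, so weighted and unweighted
estimates coincide in expectation); age trends in serum Zn; seasonal or
assay batch effects; spatial structure in inflammation. Passing tests
therefore demonstrate the correctness and calibration of the machinery
under the stated model, not the field validity of any particular survey's
estimates.

## Problem sizes and numerical choices

The test suite and the acceptance script run calibration experiments at
300–315 sites — the scale at which a national survey of this design
operates — with 30–300 replicates depending on the precision the check
needs (replicate counts follow from the sampling error of the quantity
under test: the sd of a median of 300 chi-square(1) values is about 0.06).
Linear solves use dense LAPACK factorisations of the bordered system;
covariance matrices receive a 1e-10-scale diagonal regularisation before
Cholesky in simulation only. Fitting uses analytic-free L-BFGS-B; tie
breaks and multistart grids are stated above. Degenerate inputs (constant
fields, zero IQR, empty bins, singular systems) produce warnings or
explicit errors, listed per function in the reference documentation.

## Known limitations

* Prevalence standard errors, design-effect estimation, and co-kriging
  with environmental covariates are out of scope.
* The exponential family is the only variogram model; on the sphere this
  is the safe choice, but it cannot represent, e.g., hole effects.
* Cross-validation removes one EA at a time; spatially clustered
  mis-specification may not be detected by the median SSPE alone.
* The Gaussian prediction distribution underlying exceedance probabilities
  is an assumption; skewed local distributions would call for indicator or
  lognormal approaches, deliberately not implemented.
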