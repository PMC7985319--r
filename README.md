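# znspatial

Analysis toolkit for serum zinc status in national micronutrient surveys:
inflammation adjustment, demographic-specific deficiency classification,
survey-weighted prevalence, and geostatistical mapping of zinc status on
great-circle distances.

Serum Zn is a difficult biomarker: it falls during the acute-phase
response, varies with time of blood draw and fasting, and — because diets
in subsistence settings reflect local soils and food systems — it is
spatially structured. `znspatial` implements the full analysis chain for a
cluster-sampled survey:

* **Exclusion cascade** with first-matching-reason attribution (missing
  GPS → missing meal/draw time → missing CRP/AGP → missing
  socio-demographics → analytical outliers), so the reported counts
  partition the excluded set.
* **Inflammation staging** (none / incubation / early convalescence / late
  convalescence) from CRP 5 mg/L and AGP 1 g/L thresholds, and the
  **BRINDA internal regression correction**
  `Zn_adj = exp[lnZn − β₁(lnCRP − ref₁)₊ − β₂(lnAGP − ref₂)₊]`, with
  references at the maximum of the lowest decile of each log marker.
* **Deficiency classification** against a shipped cutoff table (strict
  `<`, specific to age band, sex, draw time and fasting status) and
  survey-weighted prevalence by stratum.
* **Geostatistics on the sphere**: EA-level aggregation, Tukey
  outer-fence outlier screening, empirical variograms by the Matheron,
  Cressie–Hawkins and Dowd estimators (isotropic and directional),
  weighted-least-squares fitting of the exponential model
  `γ(h) = c₀ + c₁(1 − e^(−h/a))`, leave-one-out cross-validation with the
  median standardized squared prediction error (SSPE, expected value
  0.455 under a valid model), ordinary kriging with global or nearest-k
  neighbourhoods, and below-threshold probability maps labelled with IPCC
  calibrated likelihood phrases.
* A **synthetic survey generator** with known ground truth (spatial field
  parameters, inflammation effects, analytic deficiency probability), so
  the whole pipeline is testable without restricted survey data.

## Worked example

The numbered drivers under `analysis/` run the whole workflow on a
synthetic survey and write tables under `results/`:

```sh
Rscript analysis/01_simulate_survey.R
Rscript analysis/02_descriptive_summaries.R
Rscript analysis/03_inflammation_adjustment.R
Rscript analysis/04_deficiency_prevalence.R
Rscript analysis/05_variograms.R
Rscript analysis/06_kriging_maps.R
```

Output of a run (seed 2015):

```
simulated 3406 participants across 343 EAs
latent field: mean 60.0 ug/dL, nugget 27.0, partial sill 39.62, a 14.79 km
input 3406; excluded 315 (GPS 88, meal time 195, markers 26, socio-dem 4,
  outliers 2); retained 3091
Spearman Zn~AGP -0.13, Zn~CRP -0.10, AGP~CRP 0.40
fitted slopes: lnCRP -0.0117 (truth -0.01), lnAGP -0.0737 (truth -0.07)
national prevalence: unadjusted 59.7%, adjusted 50.9% (n = 3091)
selected matheron model (median SSPE 0.464, valid interval 0.355-0.575,
  valid: TRUE)
grid: 2745 nodes at 0.25 deg; prediction 54.3-88.8 ug/dL
```

Reading this: the exclusion report reconciles exactly
(3406 = 315 + 3091); the BRINDA regression recovers the slopes the data
were generated with; adjusting for inflammation *lowers* estimated
prevalence (inflamed records had depressed Zn); and the leave-one-out
median SSPE of 0.464 sits near the theoretical 0.455, so the fitted
exponential variogram is accepted. The same steps are available
programmatically via `run_pipeline()`, which writes a manifest with the
counts, the BRINDA fit, the chosen variogram model and the
cross-validation summary.

In R, the core calls look like:

```r
library(znspatial)
cfg  <- simulation_config(seed = 2015)
sim  <- simulate_survey(cfg)
kept <- apply_exclusions(sim$records)$retained
adj  <- brinda_augment(kept)$records
agg  <- aggregate_by_ea(adj[adj$group == "WRA", ])
vg   <- estimate_variogram(agg, lag_bins(10, 200), "matheron")
fit  <- fit_exponential_wls(vg)
cv   <- cross_validate(agg, fit)
grid <- predict_grid(agg, fit, list(lon_min = 33, lon_max = 48,
                                    lat_min = 3.5, lat_max = 14.5,
                                    res = 0.25))
grid <- exceedance_probability(grid, threshold = 70)
```

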