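# Shared settings for the analysis drivers. The synthetic survey emulates
# the structure of the 2015 national micronutrient survey: 343 EAs, four
# demographic groups, and missingness rates chosen to mirror the reported
# exclusion cascade (~3% GPS, ~5% draw time, ~0.9% inflammation markers,
# ~0.1% socio-demographics, 2 analytical outliers).

library(znspatial)

RESULTS_DIR <- "results"
DATA_DIR <- file.path(RESULTS_DIR, "data")
SEED <- 2015

survey_config <- simulation_config(
  seed = SEED,
  missingness_rates = list(gps = 0.030, draw_time = 0.051, fasting = 0,
                           crp = 0.0045, agp = 0.0045, sociodem = 0.0012),
  n_outliers = 2
)

dir.create(DATA_DIR, recursive = TRUE, showWarnings = FALSE)
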