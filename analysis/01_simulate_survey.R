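#!/usr/bin/env Rscript
# Stage 1: generate the synthetic survey that stands in for the restricted
# serum-Zn data, with known ground truth for every downstream check.

source("analysis/00_config.R")

sim <- simulate_survey(survey_config,
                       csv_path = file.path(DATA_DIR, "survey_synthetic.csv"),
                       truth_path = file.path(DATA_DIR, "ground_truth.json"))

cat(sprintf("simulated %d participants across %d EAs\n",
            nrow(sim$records), nrow(sim$ea)))
cat(sprintf("latent field: mean %.1f ug/dL, nugget %.1f, partial sill %.2f, a %.2f km\n",
            sim$truth$field$mean, sim$truth$field$nugget,
            sim$truth$field$partial_sill, sim$truth$field$distance_param))
cat(sprintf("marker elevation: CRP>5 in %.1f%%, AGP>1 in %.1f%%\n",
            100 * mean(sim$records$crp > 5, na.rm = TRUE),
            100 * mean(sim$records$agp > 1, na.rm = TRUE)))
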