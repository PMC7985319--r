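#!/usr/bin/env Rscript
# Stage 2: exclusion cascade, inflammation staging, participant summaries
# and rank correlations on the retained cohort.

source("analysis/00_config.R")

records <- read_survey(file.path(DATA_DIR, "survey_synthetic.csv"))
excl <- apply_exclusions(records)
jsonlite::write_json(excl$report,
                     file.path(RESULTS_DIR, "exclusion_report.json"),
                     auto_unbox = TRUE, digits = NA)
cat(sprintf("input %d; excluded %d (GPS %d, meal time %d, markers %d, socio-dem %d, outliers %d); retained %d\n",
            excl$report$n_input, excl$report$n_excluded,
            excl$report$missing_gps, excl$report$missing_meal_time,
            excl$report$missing_inflammation,
            excl$report$missing_sociodemographic,
            excl$report$analytical_outlier, excl$report$n_retained))

retained <- excl$retained
retained$stage <- stage_inflammation(retained$crp, retained$agp)
write_survey(retained, file.path(DATA_DIR, "retained.csv"))

summaries <- do.call(rbind, lapply(
  c("group", "residence", "head_educated", "stage", "region"),
  function(b) { s <- weighted_summary(retained, b); s$by <- b; s }))
write.csv(summaries, file.path(RESULTS_DIR, "participant_summaries.csv"),
          row.names = FALSE)
st <- summaries[summaries$by == "stage", ]
cat(sprintf("no inflammation: %.1f%% of cohort; weighted median Zn %.1f ug/dL\n",
            st$share_pct[st$stratum == "none"],
            st$median_zn[st$stratum == "none"]))

corr <- spearman_correlations(retained)
write.csv(round(corr, 3), file.path(RESULTS_DIR, "spearman.csv"))
cat(sprintf("Spearman Zn~AGP %.2f, Zn~CRP %.2f, AGP~CRP %.2f\n",
            corr["zn", "agp"], corr["zn", "crp"], corr["agp", "crp"]))
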