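#!/usr/bin/env Rscript
# Stage 4: classify serum-Zn deficiency against the age/sex/draw-time/
# fasting cutoffs and estimate survey-weighted prevalence by stratum.

source("analysis/00_config.R")

adjusted <- read_survey(file.path(DATA_DIR, "adjusted.csv"))
adjusted$zn_adjusted <- as.numeric(adjusted$zn_adjusted)
cutoffs <- load_cutoffs()

prev <- do.call(rbind, lapply(c("group", "residence", "region"), function(b) {
  p <- estimate_prevalence(adjusted, cutoffs, group_by = b)
  p$by <- b
  p[p$stratum != "national" | b == "group", ]
}))
write.csv(prev, file.path(RESULTS_DIR, "prevalence.csv"), row.names = FALSE)

nat <- prev[prev$stratum == "national", ][1, ]
cat(sprintf("national prevalence: unadjusted %.1f%%, adjusted %.1f%% (n = %d)\n",
            nat$prevalence_unadjusted, nat$prevalence_adjusted, nat$n))
grp <- prev[prev$by == "group" & prev$stratum != "national", ]
for (i in seq_len(nrow(grp))) {
  cat(sprintf("  %-4s adjusted %.1f%%\n", grp$stratum[i],
              grp$prevalence_adjusted[i]))
}
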