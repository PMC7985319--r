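# Shared fixtures, all built in code.

# EA-aggregate table with a Gaussian field drawn from `model` at n uniform
# sites in a lon/lat window (smooth component + independent nugget noise).
make_field_aggregates <- function(n, model,
                                  lon = c(36, 40), lat = c(6, 10),
                                  mean_zn = 60) {
  xy <- data.frame(ea_id = sprintf("EA%03d", seq_len(n)),
                   mean_lon = runif(n, lon[1], lon[2]),
                   mean_lat = runif(n, lat[1], lat[2]))
  cfg <- simulation_config(seed = 1, field_nugget = model$c0,
                           field_partial_sill = model$c1,
                           field_distance_param = model$a,
                           field_mean = mean_zn)
  xy$mean_zn <- simulate_zn_field(
    data.frame(lon = xy$mean_lon, lat = xy$mean_lat), cfg)
  xy$n_records <- 1L
  xy
}

# Minimal complete survey record template, recycled to n rows.
make_records <- function(n, ...) {
  if (n == 0) return(make_records(1)[0, ])
  base <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    ea_id = sprintf("EA%03d", 1 + (seq_len(n) - 1) %% 20),
    lon = 38 + (seq_len(n) %% 7) / 10, lat = 8 + (seq_len(n) %% 5) / 10,
    region = "R1", residence = "rural", group = "WRA",
    age = 30, sex = "female", draw_time = "morning", fasting = FALSE,
    zn = 60, crp = 1, agp = 0.8, weight = 1,
    head_educated = TRUE, diarrhea = FALSE, analytical_outlier = FALSE,
    stringsAsFactors = FALSE)
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

# The published exponential fit, used as a generating truth in simulations.
REFERENCE_MODEL <- list(c0 = 27.0, c1 = 39.62, a = 14.79)

# Records reproducing the published exclusion-cascade counts:
# 3373 input; 101 missing GPS, 172 missing meal time, 30 missing markers,
# 4 missing socio-demographics, 2 analytical outliers; 3064 retained.
make_exclusion_fixture <- function() {
  r <- make_records(3373)
  r$lon[1:101] <- NA
  r$draw_time[102:273] <- NA
  r$crp[274:303] <- NA
  r$region[304:307] <- NA
  r$analytical_outlier[308:309] <- TRUE
  r
}

# Records reproducing the published participant-characteristics margins:
# groups YC 519 / SAC 962 / MEN 402 / WRA 1181, residence urban 768 /
# rural 2296, inflammation stages none 2123 / incubation 70 / early 262 /
# late 609, among n = 3064.
make_table1_fixture <- function() {
  n <- 3064
  r <- make_records(n)
  r$group <- rep(c("YC", "SAC", "MEN", "WRA"), c(519, 962, 402, 1181))
  r$residence <- rep(c("urban", "rural"), c(768, 2296))
  stage_n <- c(2123, 70, 262, 609)
  r$crp <- rep(c(1, 8, 8, 1), stage_n)
  r$agp <- rep(c(0.8, 0.8, 1.5, 1.5), stage_n)
  r
}
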