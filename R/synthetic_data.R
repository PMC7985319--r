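#' Configuration for the synthetic survey generator
#'
#' Builds and validates the configuration of the synthetic micronutrient
#' survey. Defaults emulate a national cluster survey of an Ethiopia-like
#' territory: 343 enumeration areas (EAs) in a lon/lat window spanning the
#' country, 9--11 participants per EA in four demographic groups, a spatially
#' correlated serum Zn field with exponential variogram (nugget 27.0,
#' partial sill 39.62 (ug/dL)^2, distance parameter 14.79 km), and log-normal
#' CRP/AGP inflammation markers negatively associated with lnZn so that
#' inflammation adjustment is exercised.
#'
#' The acute-phase marker distributions are calibrated so that about 11% of
#' participants have elevated CRP (> 5 mg/L) and about 28% elevated AGP
#' (> 1 g/L), with rank correlation about 0.40 between the two markers and
#' about -0.14 between Zn and AGP.
#'
#' @param n_ea number of enumeration areas.
#' @param households_per_ea integer range (min, max) of participants per EA.
#' @param lon_window,lat_window numeric length-2 windows in decimal degrees.
#' @param field_nugget,field_partial_sill variance components, (ug/dL)^2.
#' @param field_distance_param exponential distance parameter, km.
#' @param field_mean mean serum Zn of the latent EA field, ug/dL.
#' @param beta_crp,beta_agp regression slopes of lnZn on lnCRP and lnAGP.
#' @param crp_lognormal_params,agp_lognormal_params `c(meanlog, sdlog)`.
#' @param marker_log_correlation correlation of lnCRP and lnAGP (Gaussian
#'   copula on the log scale; 0.416 gives Spearman ~ 0.40).
#' @param lnzn_noise_sd within-EA between-participant sd of lnZn.
#' @param missingness_rates named list of per-field missingness
#'   probabilities: `gps`, `draw_time`, `fasting`, `crp`, `agp`, `sociodem`.
#' @param demographic_mix named proportions for groups YC, SAC, MEN, WRA;
#'   must sum to 1.
#' @param n_outliers number of analytical-outlier flags to inject.
#' @param seed integer seed; mandatory, no hidden default.
#' @return a `zn_sim_config` list.
#' @export
simulation_config <- function(n_ea = 343L,
                              households_per_ea = c(9L, 11L),
                              lon_window = c(33, 48),
                              lat_window = c(3.5, 14.5),
                              field_nugget = 27.0,
                              field_partial_sill = 39.62,
                              field_distance_param = 14.79,
                              field_mean = 60,
                              beta_crp = -0.01,
                              beta_agp = -0.07,
                              crp_lognormal_params = c(-0.11, 1.4),
                              agp_lognormal_params = c(-0.262, 0.45),
                              marker_log_correlation = 0.416,
                              lnzn_noise_sd = 0.25,
                              missingness_rates = list(gps = 0, draw_time = 0,
                                                       fasting = 0, crp = 0,
                                                       agp = 0, sociodem = 0),
                              demographic_mix = c(YC = 0.169, SAC = 0.314,
                                                  MEN = 0.131, WRA = 0.386),
                              n_outliers = 0L,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory in simulation_config()")
  stopifnot(n_ea >= 1, length(households_per_ea) == 2,
            households_per_ea[1] >= 1,
            households_per_ea[2] >= households_per_ea[1],
            diff(lon_window) > 0, diff(lat_window) > 0,
            field_nugget >= 0, field_partial_sill >= 0,
            field_distance_param > 0, field_mean > 0,
            lnzn_noise_sd >= 0, n_outliers >= 0)
  rates <- unlist(missingness_rates)
  if (any(rates < 0 | rates > 1)) stop("missingness rates must be in [0, 1]")
  if (abs(sum(demographic_mix) - 1) > 1e-8)
    stop("demographic_mix proportions must sum to 1")
  if (abs(marker_log_correlation) >= 1)
    stop("marker_log_correlation must be in (-1, 1)")
  structure(list(
    n_ea = as.integer(n_ea),
    households_per_ea = as.integer(households_per_ea),
    lon_window = lon_window, lat_window = lat_window,
    field_nugget = field_nugget, field_partial_sill = field_partial_sill,
    field_distance_param = field_distance_param, field_mean = field_mean,
    beta_crp = beta_crp, beta_agp = beta_agp,
    crp_lognormal_params = crp_lognormal_params,
    agp_lognormal_params = agp_lognormal_params,
    marker_log_correlation = marker_log_correlation,
    lnzn_noise_sd = lnzn_noise_sd,
    missingness_rates = as.list(rates),
    demographic_mix = demographic_mix,
    n_outliers = as.integer(n_outliers),
    seed = as.integer(seed)
  ), class = "zn_sim_config")
}

#' Simulate enumeration-area centroids
#'
#' EA centroids are drawn uniformly over the configured lon/lat window.
#'
#' @param config a [simulation_config()].
#' @return data frame with columns `ea_id`, `lon`, `lat`.
#' @export
simulate_ea_locations <- function(config) {
  stopifnot(inherits(config, "zn_sim_config"))
  n <- config$n_ea
  if (n < 1) stop("n_ea must be at least 1")
  data.frame(
    ea_id = sprintf("EA%03d", seq_len(n)),
    lon = runif(n, config$lon_window[1], config$lon_window[2]),
    lat = runif(n, config$lat_window[1], config$lat_window[2])
  )
}

#' Simulate a Gaussian serum-Zn field at EA centroids
#'
#' Draws from a Gaussian process whose semivariance on great-circle distance
#' h is `gamma(h) = c0 + c1 * (1 - exp(-h / a))`: the spatially smooth
#' component has covariance `c1 * exp(-h / a)` between sites and the nugget
#' `c0` is realised as independent noise attached to each value.
#'
#' @param locations data frame with `lon`, `lat` (degrees).
#' @param config a [simulation_config()]; uses `field_*` entries.
#' @return numeric vector of Zn values at the sites, ug/dL.
#' @export
simulate_zn_field <- function(locations, config) {
  c0 <- config$field_nugget
  c1 <- config$field_partial_sill
  a  <- config$field_distance_param
  mu <- config$field_mean
  n <- nrow(locations)
  smooth <- numeric(n)
  if (c1 > 0) {
    d <- great_circle_matrix(locations[, c("lon", "lat")])
    sigma <- c1 * exp(-d / a)
    ch <- tryCatch(chol(sigma + diag(1e-10 * c1, n)),
                   error = function(e) stop(
                     "covariance matrix is not positive definite; ",
                     "check distances and variogram parameters", call. = FALSE))
    smooth <- drop(crossprod(ch, rnorm(n)))
  }
  nug <- if (c0 > 0) rnorm(n, 0, sqrt(c0)) else numeric(n)
  mu + smooth + nug
}

#' Simulate survey participants around EA-level Zn values
#'
#' For each EA, participants are drawn with demographic attributes from the
#' configured mix; the individual log serum Zn is
#' `lnZn = ln(EA value) + beta_crp * (lnCRP - mu_crp) + beta_agp * (lnAGP -
#' mu_agp) + noise`, centred so the marker terms do not shift the mean, which
#' makes BRINDA-style recovery of the slopes testable. Missing GPS,
#' draw-time/fasting, marker, and socio-demographic fields are injected at
#' the configured rates; sampling weights are positive.
#'
#' @param ea_values data frame with `ea_id`, `lon`, `lat`, `zn_ea` (the
#'   latent EA-level Zn, ug/dL).
#' @param config a [simulation_config()].
#' @return data frame of survey records (one row per participant).
#' @export
simulate_participants <- function(ea_values, config) {
  if (nrow(ea_values) == 0L) stop("ea_values is empty")
  groups <- names(config$demographic_mix)
  regions <- paste0("R", 1:11)
  rng <- config$households_per_ea
  n_per <- sample(seq(rng[1], rng[2]), nrow(ea_values), replace = TRUE)
  idx <- rep(seq_len(nrow(ea_values)), n_per)
  n <- length(idx)

  group <- sample(groups, n, replace = TRUE, prob = config$demographic_mix)
  age <- numeric(n)
  age[group == "YC"]  <- runif(sum(group == "YC"), 0.5, 4.99)
  age[group == "SAC"] <- runif(sum(group == "SAC"), 5, 15)
  age[group == "WRA"] <- runif(sum(group == "WRA"), 15, 49)
  age[group == "MEN"] <- runif(sum(group == "MEN"), 15, 54)
  sex <- ifelse(group == "WRA", "female",
                ifelse(group == "MEN", "male",
                       sample(c("male", "female"), n, replace = TRUE)))

  # blood-draw context; fasting only for adults drawn in the morning, so the
  # cutoff table always has a matching row
  child <- group %in% c("YC", "SAC")
  draw_time <- ifelse(runif(n) < 2 / 3, "morning", "afternoon")
  fasting <- !child & draw_time == "morning" & runif(n) < 0.25

  # correlated log-normal acute-phase markers (Gaussian copula on logs)
  rho <- config$marker_log_correlation
  z1 <- rnorm(n); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
  lncrp <- config$crp_lognormal_params[1] + config$crp_lognormal_params[2] * z1
  lnagp <- config$agp_lognormal_params[1] + config$agp_lognormal_params[2] * z2

  ea_zn <- pmax(ea_values$zn_ea[idx], 1)
  lnzn <- log(ea_zn) +
    config$beta_crp * (lncrp - config$crp_lognormal_params[1]) +
    config$beta_agp * (lnagp - config$agp_lognormal_params[1]) +
    rnorm(n, 0, config$lnzn_noise_sd)

  rec <- data.frame(
    id = sprintf("P%05d", seq_len(n)),
    ea_id = ea_values$ea_id[idx],
    lon = ea_values$lon[idx] + rnorm(n, 0, 0.002),
    lat = ea_values$lat[idx] + rnorm(n, 0, 0.002),
    region = regions[1 + (match(ea_values$ea_id[idx], ea_values$ea_id) %% 11)],
    residence = ifelse(runif(n) < 0.25, "urban", "rural"),
    group = group, age = age, sex = sex,
    draw_time = draw_time, fasting = fasting,
    zn = exp(lnzn),
    crp = exp(lncrp), agp = exp(lnagp),
    weight = runif(n, 0.5, 2),
    head_educated = runif(n) < 0.49,
    diarrhea = runif(n) < 0.15,
    analytical_outlier = FALSE
  )

  r <- config$missingness_rates
  inject <- function(k, rate) runif(n) < rate
  miss_gps <- inject("gps", r$gps %||% 0)
  rec$lon[miss_gps] <- NA_real_; rec$lat[miss_gps] <- NA_real_
  rec$draw_time[inject("draw_time", r$draw_time %||% 0)] <- NA_character_
  rec$fasting[inject("fasting", r$fasting %||% 0)] <- NA
  rec$crp[inject("crp", r$crp %||% 0)] <- NA_real_
  rec$agp[inject("agp", r$agp %||% 0)] <- NA_real_
  miss_sd <- inject("sociodem", r$sociodem %||% 0)
  rec$region[miss_sd] <- NA_character_
  if (config$n_outliers > 0) {
    k <- sample.int(n, min(config$n_outliers, n))
    rec$analytical_outlier[k] <- TRUE
  }
  rec
}

#' Generate a complete synthetic survey
#'
#' Runs [simulate_ea_locations()], [simulate_zn_field()] and
#' [simulate_participants()] under the configured seed. Optionally writes
#' the survey CSV and a ground-truth JSON (field parameters, slopes, latent
#' per-EA values).
#'
#' @param config a [simulation_config()].
#' @param csv_path,truth_path optional output paths.
#' @return list with `records` (data frame), `ea` (EA table with latent
#'   values), and `truth` (generating parameters).
#' @export
simulate_survey <- function(config, csv_path = NULL, truth_path = NULL) {
  set.seed(config$seed)
  ea <- simulate_ea_locations(config)
  ea$zn_ea <- simulate_zn_field(ea, config)
  records <- simulate_participants(ea, config)
  truth <- list(
    field = list(nugget = config$field_nugget,
                 partial_sill = config$field_partial_sill,
                 distance_param = config$field_distance_param,
                 mean = config$field_mean),
    beta_crp = config$beta_crp, beta_agp = config$beta_agp,
    lnzn_noise_sd = config$lnzn_noise_sd,
    seed = config$seed,
    ea = ea
  )
  if (!is.null(csv_path)) write_survey(records, csv_path)
  if (!is.null(truth_path)) {
    jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  }
  list(records = records, ea = ea, truth = truth)
}

#' Analytic deficiency probability under the generating model
#'
#' Probability that an individual's serum Zn falls below `cutoff` under the
#' generating Gaussian model, by integrating the within-EA log-normal
#' conditional over the Gaussian EA field (numerical quadrature). Used as an
#' oracle for prevalence estimates on synthetic cohorts.
#'
#' @param config a [simulation_config()].
#' @param cutoff threshold, ug/dL.
#' @return probability in [0, 1].
#' @export
generative_deficiency_probability <- function(config, cutoff) {
  s_field <- sqrt(config$field_nugget + config$field_partial_sill)
  s_ind <- sqrt(config$lnzn_noise_sd^2 +
                  (config$beta_crp * config$crp_lognormal_params[2])^2 +
                  (config$beta_agp * config$agp_lognormal_params[2])^2 +
                  2 * config$beta_crp * config$beta_agp *
                    config$marker_log_correlation *
                    config$crp_lognormal_params[2] *
                    config$agp_lognormal_params[2])
  f <- function(u) {
    ea <- pmax(config$field_mean + s_field * u, 1)
    pnorm((log(cutoff) - log(ea)) / s_ind) * dnorm(u)
  }
  integrate(f, -8, 8, rel.tol = 1e-8)$value
}

#' Write a survey table to CSV
#'
#' Fixed, documented header; blank cells encode missing values.
#'
#' @param records survey data frame.
#' @param path output path.
#' @export
write_survey <- function(records, path) {
  write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}
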