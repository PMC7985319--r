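#' End-to-end survey analysis pipeline
#'
#' Orchestrates the full analysis: obtain records (simulate or read CSV),
#' apply the exclusion cascade, stage inflammation, fit and apply the BRINDA
#' correction, classify deficiency and estimate weighted prevalence,
#' aggregate to EAs, screen variogram outliers, estimate variograms with all
#' requested estimators, fit exponential models by WLS, select a model by
#' cross-validation, krige a prediction grid and derive below-threshold
#' probabilities. All stage outputs are written under `out_dir`; a manifest
#' records seed, counts, the BRINDA fit, the chosen model and the
#' cross-validation summary. The same config and seed reproduce identical
#' outputs.
#'
#' @param config list with entries: one of `input_csv` or `sim_config` (a
#'   [simulation_config()]); optional `cutoffs_path`, `bins` ([lag_bins()]),
#'   `estimators` (default all three), `grid_spec` (default 0.5 degree over
#'   the data bounding box), `threshold` (default 70), `group` (demographic
#'   group mapped, default `"WRA"`), `out_dir` (required).
#' @return the manifest (invisibly also written as JSON).
#' @export
run_pipeline <- function(config) {
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline failed at stage '%s': %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  records <- stage("input", {
    if (!is.null(config$input_csv)) {
      read_survey(config$input_csv)
    } else if (!is.null(config$sim_config)) {
      sim <- simulate_survey(config$sim_config,
                             csv_path = file.path(out_dir, "survey.csv"),
                             truth_path = file.path(out_dir, "truth.json"))
      sim$records
    } else stop("config needs input_csv or sim_config")
  })

  excl <- stage("exclusions", apply_exclusions(records))
  jsonlite::write_json(excl$report, file.path(out_dir, "exclusion_report.json"),
                       auto_unbox = TRUE, digits = NA)
  retained <- excl$retained

  aug <- stage("brinda", brinda_augment(retained))
  retained <- aug$records
  jsonlite::write_json(unclass(aug$fit)[c("beta1", "beta2", "ref_lncrp",
                                          "ref_lnagp", "n_fit")],
                       file.path(out_dir, "brinda_fit.json"),
                       auto_unbox = TRUE, digits = NA)

  cutoffs <- stage("cutoffs", {
    if (is.null(config$cutoffs_path)) load_cutoffs()
    else load_cutoffs(config$cutoffs_path)
  })

  summaries <- stage("summaries", {
    by <- c("region", "group", "residence", "head_educated", "stage")
    do.call(rbind, lapply(by, function(b) {
      s <- weighted_summary(retained, b); s$by <- b; s
    }))
  })
  write.csv(summaries, file.path(out_dir, "weighted_summaries.csv"),
            row.names = FALSE)

  prev <- stage("prevalence",
                estimate_prevalence(retained, cutoffs, group_by = "group"))
  write.csv(prev, file.path(out_dir, "prevalence.csv"), row.names = FALSE)

  corr <- stage("correlations", spearman_correlations(retained))
  write.csv(corr, file.path(out_dir, "spearman.csv"))

  grp <- config$group %||% "WRA"
  spatial_rec <- retained[retained$group == grp, , drop = FALSE]
  agg <- stage("aggregation", aggregate_by_ea(spatial_rec))

  outl <- stage("outliers", tukey_outliers(agg$mean_zn))
  agg_vg <- agg[!outl$mask, , drop = FALSE]

  bins <- config$bins %||% lag_bins()
  estimators <- config$estimators %||% c("matheron", "cressie_hawkins", "dowd")
  vgs <- stage("variograms", {
    setNames(lapply(estimators, function(e)
      estimate_variogram(agg_vg, bins, estimator = e)), estimators)
  })
  vg_tab <- do.call(rbind, lapply(names(vgs), function(e) {
    v <- as.data.frame(vgs[[e]]); v$estimator <- e; v
  }))
  write.csv(vg_tab, file.path(out_dir, "variograms.csv"), row.names = FALSE)

  fits <- stage("wls_fit", lapply(vgs, fit_exponential_wls))
  sel <- stage("model_selection", select_model(fits, agg_vg))
  jsonlite::write_json(
    list(chosen = sel$chosen, is_valid = sel$is_valid,
         model = sel$model[c("c0", "c1", "a", "effective_range")],
         median_sspe = sel$cv$median_sspe, trail = sel$trail),
    file.path(out_dir, "model_selection.json"), auto_unbox = TRUE, digits = NA)
  write.csv(data.frame(error = sel$cv$errors, theta = sel$cv$theta),
            file.path(out_dir, "cv_errors.csv"), row.names = FALSE)

  # outliers reinstated for prediction
  gs <- config$grid_spec %||% list(
    lon_min = floor(min(agg$mean_lon)), lon_max = ceiling(max(agg$mean_lon)),
    lat_min = floor(min(agg$mean_lat)), lat_max = ceiling(max(agg$mean_lat)),
    res = 0.5)
  grid <- stage("kriging", predict_grid(agg, sel$model, gs))
  grid <- stage("probability",
                exceedance_probability(grid, config$threshold %||% 70))
  write.csv(grid, file.path(out_dir, "grid_predictions.csv"),
            row.names = FALSE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("znspatial")),
    seed = config$sim_config$seed %||% NA,
    n_input = excl$report$n_input,
    n_excluded = excl$report$n_excluded,
    n_retained = excl$report$n_retained,
    brinda = unclass(aug$fit)[c("beta1", "beta2", "ref_lncrp", "ref_lnagp")],
    spatial_group = grp,
    n_ea = nrow(agg),
    n_variogram_outliers = sum(outl$mask),
    chosen_estimator = sel$chosen,
    model = sel$model[c("c0", "c1", "a", "effective_range")],
    median_sspe = sel$cv$median_sspe,
    model_valid = sel$is_valid,
    grid_nodes = nrow(grid),
    grid_mean_prediction = mean(grid$prediction),
    threshold = config$threshold %||% 70
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
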