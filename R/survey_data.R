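SURVEY_COLUMNS <- c("id", "ea_id", "lon", "lat", "region", "residence",
                    "group", "age", "sex", "draw_time", "fasting", "zn",
                    "crp", "agp", "weight", "head_educated", "diarrhea")

#' Read a survey CSV
#'
#' Reads a participant-level survey table with the documented header (as
#' written by [write_survey()]). Blank cells become missing values; the
#' optional `analytical_outlier` column defaults to `FALSE` when absent.
#'
#' @param path CSV path.
#' @return data frame of typed survey records.
#' @export
read_survey <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  stop_if_missing_cols(df, SURVEY_COLUMNS, where = basename(path))
  num_cols <- c("lon", "lat", "age", "zn", "crp", "agp", "weight")
  for (cc in num_cols) {
    v <- df[[cc]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- !is.na(v) & is.na(vn)
      if (any(bad)) {
        warning(sprintf("%d unparseable value(s) in column '%s' set to NA",
                        sum(bad), cc))
      }
      df[[cc]] <- vn
    }
  }
  for (cc in c("fasting", "head_educated", "diarrhea")) {
    df[[cc]] <- as.logical(df[[cc]])
  }
  if (is.null(df$analytical_outlier)) df$analytical_outlier <- FALSE
  df$analytical_outlier <- as.logical(df$analytical_outlier)
  df$analytical_outlier[is.na(df$analytical_outlier)] <- FALSE
  ok_lat <- is.na(df$lat) | (df$lat >= -90 & df$lat <= 90)
  ok_lon <- is.na(df$lon) | (df$lon >= -180 & df$lon < 360)
  if (!all(ok_lat & ok_lon)) stop("unparseable or out-of-range coordinates")
  if (any(!is.na(df$zn) & df$zn <= 0)) stop("serum Zn must be positive")
  if (any(!is.na(df$weight) & df$weight <= 0)) stop("weights must be positive")
  df
}

#' Apply the exclusion cascade
#'
#' Records are dropped, in order, for: missing GPS coordinates; missing
#' meal/draw time (either draw time or fasting status absent); missing
#' inflammation biomarker (CRP and/or AGP); missing socio-demographic data
#' (region, residence, group, age or sex); analytical-outlier flag. Each
#' exclusion is attributed to the first matching reason only, so the counts
#' partition the excluded set.
#'
#' @param records survey data frame.
#' @return list with `retained` (data frame) and `report` (exclusion counts).
#' @export
apply_exclusions <- function(records) {
  n_input <- nrow(records)
  reasons <- rep(NA_character_, n_input)
  flag <- function(cond, label) {
    cond[is.na(cond)] <- FALSE
    reasons[is.na(reasons) & cond] <<- label
  }
  flag(is.na(records$lon) | is.na(records$lat), "missing_gps")
  flag(is.na(records$draw_time) | is.na(records$fasting), "missing_meal_time")
  flag(is.na(records$crp) | is.na(records$agp), "missing_inflammation")
  flag(is.na(records$region) | is.na(records$residence) |
         is.na(records$group) | is.na(records$age) | is.na(records$sex),
       "missing_sociodemographic")
  flag(records$analytical_outlier, "analytical_outlier")
  keep <- is.na(reasons)
  labels <- c("missing_gps", "missing_meal_time", "missing_inflammation",
              "missing_sociodemographic", "analytical_outlier")
  counts <- vapply(labels, function(l) sum(reasons == l, na.rm = TRUE),
                   integer(1))
  report <- c(list(n_input = n_input), as.list(counts),
              list(n_excluded = sum(!keep), n_retained = sum(keep)))
  list(retained = records[keep, , drop = FALSE], report = report)
}

#' Stage inflammation from CRP and AGP
#'
#' Four-way acute-phase staging with thresholds CRP 5 mg/L and AGP 1 g/L:
#' none (CRP <= 5, AGP <= 1), incubation (CRP > 5, AGP <= 1), early
#' convalescence (CRP > 5, AGP > 1), late convalescence (CRP <= 5, AGP > 1).
#' The partition is exhaustive: AGP exactly 1 with elevated CRP stages as
#' incubation.
#'
#' @param crp CRP in mg/L (vectorised).
#' @param agp AGP in g/L.
#' @return character vector of stages.
#' @export
stage_inflammation <- function(crp, agp) {
  if (anyNA(crp) || anyNA(agp)) stop("both CRP and AGP must be present")
  if (any(crp < 0) || any(agp < 0)) stop("markers must be non-negative")
  ifelse(crp > 5,
         ifelse(agp > 1, "early_convalescence", "incubation"),
         ifelse(agp > 1, "late_convalescence", "none"))
}

#' Weighted summary of serum Zn by stratum
#'
#' For each level of `group_by`, reports n, the stratum's percentage share of
#' records, and the survey-weighted mean and weighted median of unadjusted
#' (and, when present, adjusted) serum Zn. Empty strata of a factor input are
#' reported with `n = 0` and no estimates.
#'
#' @param records survey data frame (needs `zn`, `weight`; `zn_adjusted`
#'   optional).
#' @param group_by name of the stratifying column, or `NULL` for a single
#'   national row.
#' @return data frame, one row per stratum.
#' @export
weighted_summary <- function(records, group_by = NULL) {
  if (any(records$weight <= 0, na.rm = TRUE)) stop("weights must be positive")
  strata <- if (is.null(group_by)) {
    factor(rep("national", nrow(records)))
  } else {
    stop_if_missing_cols(records, group_by, "records")
    v <- records[[group_by]]
    if (is.factor(v)) v else factor(v)  # factors keep declared empty levels
  }
  total <- nrow(records)
  out <- lapply(levels(strata), function(lev) {
    r <- records[which(strata == lev), , drop = FALSE]
    row <- data.frame(stratum = lev, n = nrow(r),
                      share_pct = if (total > 0) 100 * nrow(r) / total else NA_real_,
                      mean_zn = NA_real_, median_zn = NA_real_,
                      mean_zn_adjusted = NA_real_, median_zn_adjusted = NA_real_)
    if (nrow(r) > 0) {
      row$mean_zn <- weighted_mean(r$zn, r$weight)
      row$median_zn <- weighted_median(r$zn, r$weight)
      if (!is.null(r$zn_adjusted)) {
        row$mean_zn_adjusted <- weighted_mean(r$zn_adjusted, r$weight)
        row$median_zn_adjusted <- weighted_median(r$zn_adjusted, r$weight)
      }
    }
    row
  })
  do.call(rbind, out)
}

#' Spearman rank correlations among survey variables
#'
#' Pairwise-complete Spearman correlations (average ranks for ties),
#' unweighted. Logical columns are coerced to 0/1.
#'
#' @param records survey data frame.
#' @param variables column names to correlate.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_correlations <- function(records,
                                  variables = c("zn", "agp", "crp", "age",
                                                "diarrhea")) {
  stop_if_missing_cols(records, variables, "records")
  x <- records[variables]
  x[] <- lapply(x, function(v) as.numeric(v))
  n_complete <- sum(complete.cases(x))
  if (n_complete < 3) stop("fewer than 3 complete observations")
  cor(as.matrix(x), method = "spearman", use = "pairwise.complete.obs")
}
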