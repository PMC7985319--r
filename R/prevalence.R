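#' Load the serum-Zn deficiency cutoff table
#'
#' The cutoffs depend on age band (< 10 y vs >= 10 y), sex (for the older
#' band), time of blood draw, and fasting status; classification is a strict
#' `<` comparison. The table ships as a version-controlled CSV in
#' `inst/extdata/zinc_cutoffs.csv` and can be replaced by the user.
#'
#' @param path CSV path; default the packaged table.
#' @return data frame with columns `age_band`, `sex`, `draw_time`,
#'   `fasting`, `cutoff`.
#' @export
load_cutoffs <- function(path = system.file("extdata", "zinc_cutoffs.csv",
                                            package = "znspatial")) {
  ct <- read.csv(path, stringsAsFactors = FALSE)
  stop_if_missing_cols(ct, c("age_band", "sex", "draw_time", "fasting",
                             "cutoff"), "cutoff table")
  ct$fasting <- as.logical(ct$fasting)
  if (any(ct$cutoff <= 0)) stop("cutoffs must be positive")
  key <- paste(ct$age_band, ct$sex, ct$draw_time, ct$fasting)
  if (anyDuplicated(key)) stop("duplicate cutoff rows")
  ct
}

#' Classify serum-Zn deficiency
#'
#' Deficient iff `zn < cutoff` (strict), with the cutoff row selected by age
#' band (`age < 10` uses the child cutoffs regardless of sex; `age >= 10`
#' uses the sex-specific rows), draw time and fasting status. Combinations
#' without a defined cutoff (e.g. afternoon fasting) raise an error rather
#' than defaulting silently.
#'
#' @param zn serum Zn, ug/dL (vectorised; adjusted or unadjusted).
#' @param age years; `sex` "male"/"female"; `draw_time` "morning"/
#'   "afternoon"; `fasting` logical.
#' @param sex,draw_time,fasting classification context, recycled.
#' @param cutoffs a [load_cutoffs()] table.
#' @return logical vector.
#' @export
classify_deficiency <- function(zn, age, sex, draw_time, fasting,
                                cutoffs = load_cutoffs()) {
  n <- length(zn)
  age <- rep_len(age, n); sex <- rep_len(sex, n)
  draw_time <- rep_len(draw_time, n); fasting <- rep_len(fasting, n)
  if (anyNA(zn) || anyNA(age) || anyNA(sex) || anyNA(draw_time) ||
      anyNA(fasting)) {
    stop("classification context must be complete (no missing fields)")
  }
  band <- ifelse(age < 10, "<10", ">=10")
  sex_key <- ifelse(band == "<10", "any", sex)
  key <- paste(band, sex_key, draw_time, fasting)
  tab_key <- paste(cutoffs$age_band, cutoffs$sex, cutoffs$draw_time,
                   cutoffs$fasting)
  idx <- match(key, tab_key)
  if (anyNA(idx)) {
    bad <- unique(key[is.na(idx)])
    stop("no cutoff defined for: ", paste(bad, collapse = "; "))
  }
  zn < cutoffs$cutoff[idx]
}

#' Survey-weighted prevalence of Zn deficiency by stratum
#'
#' Classifies each record against the cutoff table for both unadjusted and
#' (when present) BRINDA-adjusted Zn and reports the weighted percentage
#' deficient per stratum, plus a national row.
#'
#' @param records survey records with classification context, `zn`,
#'   optionally `zn_adjusted`, and `weight`.
#' @param cutoffs a [load_cutoffs()] table.
#' @param group_by stratifying column name, or `NULL` for national only.
#' @return data frame with `stratum`, `n`, `prevalence_unadjusted`,
#'   `prevalence_adjusted` (percent).
#' @export
estimate_prevalence <- function(records, cutoffs = load_cutoffs(),
                                group_by = NULL) {
  def_u <- classify_deficiency(records$zn, records$age, records$sex,
                               records$draw_time, records$fasting, cutoffs)
  def_a <- if (!is.null(records$zn_adjusted)) {
    classify_deficiency(records$zn_adjusted, records$age, records$sex,
                        records$draw_time, records$fasting, cutoffs)
  } else rep(NA, nrow(records))
  strata <- if (is.null(group_by)) {
    factor(rep("national", nrow(records)))
  } else factor(records[[group_by]])
  one <- function(lev) {
    i <- which(strata == lev)
    w <- records$weight[i]
    data.frame(
      stratum = lev, n = length(i),
      prevalence_unadjusted =
        if (length(i)) 100 * sum(w * def_u[i]) / sum(w) else NA_real_,
      prevalence_adjusted =
        if (length(i) && !anyNA(def_a[i]))
          100 * sum(w * def_a[i]) / sum(w) else NA_real_)
  }
  res <- do.call(rbind, lapply(levels(strata), one))
  if (!is.null(group_by)) {
    nat <- estimate_prevalence(records, cutoffs, group_by = NULL)
    res <- rbind(res, nat)
  }
  res
}
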