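#' Aggregate survey records to enumeration areas
#'
#' Unweighted mean of the chosen Zn column and of the coordinates per EA —
#' the spatial support used for all variogram estimation and kriging.
#'
#' @param records survey records with `ea_id`, `lon`, `lat`.
#' @param value_col Zn column to average (default `"zn_adjusted"`).
#' @param sanity_radius_km warn if records within one EA spread farther than
#'   this from their mean position.
#' @return data frame with `ea_id`, `mean_zn`, `mean_lon`, `mean_lat`,
#'   `n_records`.
#' @export
aggregate_by_ea <- function(records, value_col = "zn_adjusted",
                            sanity_radius_km = 25) {
  stop_if_missing_cols(records, c("ea_id", "lon", "lat", value_col),
                       "records")
  if (anyNA(records$lon) || anyNA(records$lat)) {
    stop("records with missing coordinates must be excluded before aggregation")
  }
  sp <- split(seq_len(nrow(records)), records$ea_id)
  out <- lapply(names(sp), function(ea) {
    i <- sp[[ea]]
    m_lon <- mean(records$lon[i]); m_lat <- mean(records$lat[i])
    spread <- max(great_circle_distance(
      cbind(records$lon[i], records$lat[i]), c(m_lon, m_lat)))
    if (spread > sanity_radius_km) {
      warning(sprintf("EA %s spreads %.1f km around its centroid", ea, spread))
    }
    data.frame(ea_id = ea, mean_zn = mean(records[[value_col]][i]),
               mean_lon = m_lon, mean_lat = m_lat, n_records = length(i))
  })
  do.call(rbind, out)
}

#' Probable outliers by Tukey's outer fences
#'
#' Fences at `lower hinge - 3 IQR` and `upper hinge + 3 IQR`, hinges from
#' `fivenum()`; values strictly outside are flagged as probable outliers.
#' Flagged values are withheld from variogram estimation and reinstated for
#' kriging prediction.
#'
#' @param values numeric, `n >= 4`.
#' @return list with logical `mask` (TRUE = probable outlier) and `fences`.
#' @export
tukey_outliers <- function(values) {
  if (length(values) < 4) stop("need at least 4 values")
  fn <- fivenum(values)
  iqr <- fn[4] - fn[2]
  if (iqr == 0) {
    warning("zero interquartile range; no outliers flagged")
    return(list(mask = rep(FALSE, length(values)),
                fences = c(lower = -Inf, upper = Inf)))
  }
  fences <- c(lower = fn[2] - 3 * iqr, upper = fn[4] + 3 * iqr)
  list(mask = values < fences[1] | values > fences[2], fences = fences)
}

#' Lag bin specification
#'
#' Half-open bins `[lower, upper)` in km; pairs at or beyond the maximum lag
#' are discarded.
#'
#' @param width bin width, km.
#' @param max_lag maximum lag, km.
#' @return data frame with `lower`, `upper`, `mid`.
#' @export
lag_bins <- function(width = 10, max_lag = 200) {
  stopifnot(width > 0, max_lag > width)
  lower <- seq(0, max_lag - width, by = width)
  data.frame(lower = lower, upper = lower + width, mid = lower + width / 2)
}

#' Empirical variogram on great-circle distances
#'
#' Binned semivariance estimates over EA aggregates, with the classical
#' Matheron estimator or the robust Cressie-Hawkins or Dowd estimators.
#' For pair differences d within a bin of N pairs:
#' \itemize{
#'   \item matheron: `sum(d^2) / (2 N)`
#'   \item cressie_hawkins: `(mean(sqrt(|d|)))^4 / (2 (0.457 + 0.494 / N))`
#'   \item dowd: `2.198 * median(|d|)^2 / 2`
#' }
#' Optionally pairs are first assigned to bearing sectors (with 180-degree
#' folding) for a directional variogram.
#'
#' @param aggregates data frame from [aggregate_by_ea()] (or any table with
#'   `mean_zn`, `mean_lon`, `mean_lat`).
#' @param bins a [lag_bins()] table.
#' @param estimator `"matheron"`, `"cressie_hawkins"` or `"dowd"`.
#' @param direction_sectors optional numeric vector of sector centres in
#'   degrees (e.g. `c(0, 45, 90, 135)`); sectors span `180/length` degrees
#'   each after folding bearings modulo 180.
#' @return object of class `zn_variogram`: data frame with `lower`, `upper`,
#'   `mid`, `n_pairs`, `gamma` (NA for empty bins) and, for directional
#'   variograms, `sector`; attribute `estimator`.
#' @export
estimate_variogram <- function(aggregates, bins = lag_bins(),
                               estimator = c("matheron", "cressie_hawkins",
                                             "dowd"),
                               direction_sectors = NULL) {
  estimator <- match.arg(estimator)
  z <- aggregates$mean_zn
  n <- length(z)
  if (n < 2) stop("need at least 2 aggregates")
  coords <- cbind(aggregates$mean_lon, aggregates$mean_lat)
  d <- great_circle_matrix(coords)
  iu <- which(upper.tri(d), arr.ind = TRUE)
  h <- d[upper.tri(d)]
  dz <- z[iu[, 1]] - z[iu[, 2]]
  keep <- h < max(bins$upper)
  h <- h[keep]; dz <- dz[keep]; iu <- iu[keep, , drop = FALSE]

  sector <- NULL
  if (!is.null(direction_sectors)) {
    b <- bearing(coords[iu[, 1], , drop = FALSE],
                 coords[iu[, 2], , drop = FALSE]) %% 180
    half <- 180 / length(direction_sectors) / 2
    sec <- rep(NA_integer_, length(b))
    for (k in seq_along(direction_sectors)) {
      ctr <- direction_sectors[k] %% 180
      dd <- pmin(abs(b - ctr), 180 - abs(b - ctr))
      sec[dd < half | (dd == half & is.na(sec))] <- k
    }
    sector <- sec
  }

  est_fun <- switch(estimator,
    matheron = function(d) sum(d^2) / (2 * length(d)),
    cressie_hawkins = function(d) {
      N <- length(d)
      (mean(sqrt(abs(d))))^4 / (2 * (0.457 + 0.494 / N))
    },
    dowd = function(d) 2.198 * median(abs(d))^2 / 2)

  one_set <- function(hh, dd, sec_label = NULL) {
    res <- bins
    res$n_pairs <- 0L
    res$gamma <- NA_real_
    bi <- findInterval(hh, c(bins$lower, max(bins$upper)),
                       rightmost.closed = FALSE)
    for (j in seq_len(nrow(bins))) {
      in_bin <- bi == j
      res$n_pairs[j] <- sum(in_bin)
      if (res$n_pairs[j] > 0) res$gamma[j] <- est_fun(dd[in_bin])
    }
    if (!is.null(sec_label)) res$sector <- sec_label
    res
  }

  out <- if (is.null(sector)) {
    one_set(h, dz)
  } else {
    do.call(rbind, lapply(seq_along(direction_sectors), function(k) {
      i <- which(sector == k)
      one_set(h[i], dz[i], direction_sectors[k])
    }))
  }
  if (all(out$n_pairs == 0)) stop("all lag bins are empty")
  structure(out, estimator = estimator, class = c("zn_variogram",
                                                  class(out)))
}

#' Exponential semivariance model
#'
#' `gamma(h) = c0 + c1 * (1 - exp(-h / a))` for `h > 0`, `gamma(0) = 0`
#' (exact-interpolation convention: the nugget is micro-scale plus
#' measurement variance that vanishes at a coincident point).
#'
#' @param h lag distances, km.
#' @param model list or vector with `c0`, `c1`, `a`.
#' @return semivariances.
#' @export
exponential_semivariance <- function(h, model) {
  g <- model$c0 + model$c1 * (1 - exp(-h / model$a))
  g[h == 0] <- 0
  g
}

#' Fit an exponential variogram model by weighted least squares
#'
#' Minimises `sum_j w_j (gammahat_j - gamma(h_j; c0, c1, a))^2` over bins
#' with pairs, with Cressie weights `w_j = N_j / gamma(h_j; theta)^2`
#' (iteratively reweighted) or plain-N weights. Parameters are constrained
#' to `c0 >= 0`, `c1 >= 0`, `a > 0` by bounded optimisation on
#' `(c0, c1, ln a)` with a multistart grid on `a`; ties are broken by lowest
#' objective, then smallest `a`.
#'
#' @param estimate a [estimate_variogram()] result (isotropic).
#' @param weighting `"cressie"` (N / gamma^2) or `"npairs"`.
#' @param a_starts multistart grid for the distance parameter, km.
#' @param max_iter reweighting iterations for the Cressie scheme.
#' @return object of class `zn_variogram_model`: list with `c0`, `c1`, `a`,
#'   `effective_range` (3a), `objective`, `converged`, `n_bins`.
#' @export
fit_exponential_wls <- function(estimate, weighting = c("cressie", "npairs"),
                                a_starts = c(5, 10, 20, 40, 80),
                                max_iter = 10) {
  weighting <- match.arg(weighting)
  ok <- !is.na(estimate$gamma) & estimate$n_pairs > 0
  h <- estimate$mid[ok]; g <- estimate$gamma[ok]; np <- estimate$n_pairs[ok]
  if (length(h) < 3) stop("need at least 3 non-empty bins")
  sill0 <- max(mean(g), 1e-8)

  obj_for <- function(w) function(p) {
    m <- list(c0 = p[1], c1 = p[2], a = exp(p[3]))
    sum(w * (g - (m$c0 + m$c1 * (1 - exp(-h / m$a))))^2)
  }
  fit_one <- function(a0) {
    p <- c(sill0 / 2, sill0 / 2, log(a0))
    w <- np
    conv <- FALSE
    for (it in seq_len(if (weighting == "cressie") max_iter else 1L)) {
      o <- optim(p, obj_for(w), method = "L-BFGS-B",
                 lower = c(0, 0, log(0.1)),
                 upper = c(10 * sill0, 10 * sill0, log(5 * max(h))))
      p_new <- o$par
      conv <- o$convergence == 0
      if (weighting == "cressie") {
        gm <- pmax(p_new[1] + p_new[2] * (1 - exp(-h / exp(p_new[3]))), 1e-8)
        w <- np / gm^2
      }
      if (max(abs(p_new - p)) < 1e-10) { p <- p_new; break }
      p <- p_new
    }
    list(par = p, value = obj_for(w)(p), converged = conv)
  }
  fits <- lapply(a_starts, fit_one)
  vals <- vapply(fits, `[[`, numeric(1), "value")
  avals <- vapply(fits, function(f) exp(f$par[3]), numeric(1))
  best <- order(vals, avals)[1]
  p <- fits[[best]]$par
  model <- structure(list(c0 = p[1], c1 = p[2], a = exp(p[3]),
                          effective_range = 3 * exp(p[3]),
                          objective = fits[[best]]$value,
                          converged = fits[[best]]$converged,
                          n_bins = length(h),
                          estimator = attr(estimate, "estimator") %||% NA),
                     class = "zn_variogram_model")
  if (model$c1 < 1e-6 * (model$c0 + model$c1 + 1e-12)) {
    warning("fitted partial sill is ~0: pure-nugget model")
  }
  model
}
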