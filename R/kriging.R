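#' Ordinary kriging at target locations
#'
#' Solves the ordinary kriging system in semivariance form with the
#' unbiasedness constraint (weights sum to 1), with all lags measured as
#' great-circle distances. The prediction is `sum(lambda_i z_i)` and the
#' kriging variance `sum(lambda_i gamma(h_i0)) + psi` where `psi` is the
#' Lagrange multiplier. Coincident target and datum yields exact
#' interpolation (`gamma(0) = 0`): the prediction equals the datum with zero
#' kriging variance.
#'
#' @param targets matrix/data frame with columns (lon, lat), or a single
#'   `c(lon, lat)`.
#' @param aggregates data frame with `mean_lon`, `mean_lat`, `mean_zn`.
#' @param model a [fit_exponential_wls()] model (or list with `c0`, `c1`,
#'   `a`).
#' @param neighborhood `Inf` for global kriging (default) or an integer k
#'   for nearest-k neighbourhoods.
#' @return data frame with `lon`, `lat`, `prediction`, `kriging_variance`,
#'   `lagrange`; attribute `weights` (matrix, one row per target; global
#'   kriging only).
#' @export
krige <- function(targets, aggregates, model, neighborhood = Inf) {
  targets <- as_point_matrix(targets)
  check_coords(targets)
  n <- nrow(aggregates)
  if (n < 1) stop("need at least 1 data point")
  coords <- cbind(aggregates$mean_lon, aggregates$mean_lat)
  z <- aggregates$mean_zn
  d <- great_circle_matrix(coords)
  if (n > 1 && min(d[upper.tri(d)]) == 0) {
    stop("duplicate data locations: kriging system is singular")
  }
  global <- !is.finite(neighborhood) || neighborhood >= n

  solve_ok <- function(gamma_mat, gamma0) {
    m <- nrow(gamma_mat)
    B <- rbind(cbind(gamma_mat, 1), c(rep(1, m), 0))
    sol <- solve(B, rbind(gamma0, 1))
    list(lambda = sol[seq_len(m), , drop = FALSE],
         psi = sol[m + 1, ])
  }

  d0 <- great_circle_distance_pairs(targets, coords)  # ntarg x n
  if (global) {
    G <- exponential_semivariance(d, model)
    diag(G) <- 0
    g0 <- exponential_semivariance(d0, model)
    sol <- solve_ok(G, t(g0))
    lambda <- t(sol$lambda)                      # ntarg x n
    pred <- drop(lambda %*% z)
    kv <- rowSums(lambda * g0) + sol$psi
    out <- data.frame(lon = targets[, 1], lat = targets[, 2],
                      prediction = pred,
                      kriging_variance = pmax(kv, 0),
                      lagrange = sol$psi)
    attr(out, "weights") <- lambda
  } else {
    k <- as.integer(neighborhood)
    res <- lapply(seq_len(nrow(targets)), function(i) {
      nb <- order(d0[i, ])[seq_len(k)]
      G <- exponential_semivariance(d[nb, nb, drop = FALSE], model)
      diag(G) <- 0
      g0 <- exponential_semivariance(d0[i, nb], model)
      s <- solve_ok(G, cbind(g0))
      lam <- drop(s$lambda)
      data.frame(lon = targets[i, 1], lat = targets[i, 2],
                 prediction = sum(lam * z[nb]),
                 kriging_variance = max(sum(lam * g0) + s$psi, 0),
                 lagrange = s$psi)
    })
    out <- do.call(rbind, res)
  }
  # exactness at coincident locations
  hit <- which(d0 == 0, arr.ind = TRUE)
  if (nrow(hit)) {
    out$prediction[hit[, 1]] <- z[hit[, 2]]
    out$kriging_variance[hit[, 1]] <- 0
  }
  out
}

# ntarg x ndata great-circle distance matrix
great_circle_distance_pairs <- function(p, q) {
  p <- rbind(as.matrix(p)); q <- rbind(as.matrix(q))
  phi1 <- p[, 2] * pi / 180; lam1 <- p[, 1] * pi / 180
  phi2 <- q[, 2] * pi / 180; lam2 <- q[, 1] * pi / 180
  dphi <- outer(phi1, phi2, "-")
  dlam <- outer(lam1, lam2, "-")
  a <- sin(dphi / 2)^2 + (cos(phi1) %o% cos(phi2)) * sin(dlam / 2)^2
  a[a < 0] <- 0; a[a > 1] <- 1
  2 * EARTH_RADIUS_KM * asin(sqrt(a))
}

#' Leave-one-out cross-validation of a variogram model
#'
#' Each EA aggregate is removed in turn and predicted from the rest by
#' ordinary kriging under `model`; the squared error is standardised by the
#' kriging variance. Under a valid model with normal kriging errors the
#' standardised squared errors are chi-square with 1 df, so their median has
#' expected value 0.455; a median inside (0.355, 0.575) is taken as
#' consistent with a valid model.
#'
#' @param aggregates EA table (>= 10 sites recommended).
#' @param model variogram model.
#' @param valid_interval acceptance interval for the median SSPE.
#' @param method `"direct"` uses the classical shortcut through the inverse
#'   of the bordered kriging matrix (error `(H z)_i / H_ii`, variance
#'   `-1 / H_ii`), algebraically identical to removing each site and
#'   re-kriging; `"refit"` does the explicit leave-one-out loop.
#' @return object of class `zn_cv`: list with `errors`, `kriging_variance`,
#'   `theta` (standardised squared errors), `median_sspe`, `valid_interval`,
#'   `is_valid`.
#' @export
cross_validate <- function(aggregates, model,
                           valid_interval = c(0.355, 0.575),
                           method = c("direct", "refit")) {
  method <- match.arg(method)
  n <- nrow(aggregates)
  if (n < 3) stop("need at least 3 sites")
  coords <- cbind(aggregates$mean_lon, aggregates$mean_lat)
  z <- aggregates$mean_zn
  d <- great_circle_matrix(coords)
  if (min(d[upper.tri(d)]) == 0) stop("duplicate data locations")
  G <- exponential_semivariance(d, model)
  diag(G) <- 0
  if (method == "direct") {
    B <- rbind(cbind(G, 1), c(rep(1, n), 0))
    H <- solve(B)
    hii <- diag(H)[seq_len(n)]
    err <- drop(H[seq_len(n), ] %*% c(z, 0)) / hii
    kv <- -1 / hii
  } else {
    err <- kv <- numeric(n)
    for (i in seq_len(n)) {
      Gi <- G[-i, -i, drop = FALSE]
      g0 <- G[-i, i]
      m <- n - 1
      B <- rbind(cbind(Gi, 1), c(rep(1, m), 0))
      sol <- solve(B, c(g0, 1))
      lam <- sol[seq_len(m)]
      err[i] <- z[i] - sum(lam * z[-i])
      kv[i] <- sum(lam * g0) + sol[m + 1]
    }
  }
  if (any(kv <= 0)) {
    stop("non-positive leave-one-out kriging variance; model is degenerate")
  }
  theta <- err^2 / kv
  med <- median(theta)
  structure(list(errors = err, kriging_variance = kv, theta = theta,
                 median_sspe = med, valid_interval = valid_interval,
                 is_valid = med > valid_interval[1] & med < valid_interval[2]),
            class = "zn_cv")
}

#' Select a variogram model by cross-validation
#'
#' The Matheron estimator is the most statistically efficient, so its fitted
#' model is accepted outright if its median SSPE lies in the validity
#' interval. Otherwise the models fitted to the robust estimators are also
#' cross-validated and the one with median SSPE closest to 0.455 is chosen.
#' If none is valid the closest model is returned flagged invalid.
#'
#' @param fits named list of variogram models; must include `matheron`.
#' @param aggregates EA table used for cross-validation.
#' @param valid_interval validity interval for the median SSPE.
#' @return list with `chosen` (estimator name), `model`, `cv` (its
#'   cross-validation), `is_valid`, and `trail` (per-estimator median SSPE
#'   examined, in order).
#' @export
select_model <- function(fits, aggregates,
                         valid_interval = c(0.355, 0.575)) {
  if (is.null(fits$matheron)) stop("a Matheron fit is required")
  trail <- list()
  cv_m <- cross_validate(aggregates, fits$matheron, valid_interval)
  trail$matheron <- cv_m$median_sspe
  if (cv_m$is_valid) {
    return(list(chosen = "matheron", model = fits$matheron, cv = cv_m,
                is_valid = TRUE, trail = trail))
  }
  others <- setdiff(names(fits), "matheron")
  cvs <- list(matheron = cv_m)
  for (nm in others) {
    cvs[[nm]] <- cross_validate(aggregates, fits[[nm]], valid_interval)
    trail[[nm]] <- cvs[[nm]]$median_sspe
  }
  meds <- vapply(cvs, `[[`, numeric(1), "median_sspe")
  best <- names(which.min(abs(meds - 0.455)))
  list(chosen = best, model = fits[[best]], cv = cvs[[best]],
       is_valid = cvs[[best]]$is_valid, trail = trail)
}

#' Ordinary kriging over a lon/lat grid
#'
#' Predictions and kriging variances at the nodes of a regular grid.
#' Aggregates previously withheld as variogram outliers should be reinstated
#' by the caller before prediction.
#'
#' @param aggregates EA table.
#' @param model variogram model.
#' @param grid_spec list with `lon_min`, `lon_max`, `lat_min`, `lat_max`,
#'   `res` (degrees).
#' @param node_cap refuse grids with more nodes than this.
#' @param neighborhood passed to [krige()].
#' @return data frame of kriging results, one row per node.
#' @export
predict_grid <- function(aggregates, model, grid_spec, node_cap = 1e6,
                         neighborhood = Inf) {
  gs <- grid_spec
  lon <- seq(gs$lon_min, gs$lon_max, by = gs$res)
  lat <- seq(gs$lat_min, gs$lat_max, by = gs$res)
  if (length(lon) * length(lat) > node_cap) {
    stop(sprintf("grid has %d nodes, above the cap of %g; coarsen res",
                 length(lon) * length(lat), node_cap))
  }
  nodes <- as.matrix(expand.grid(lon = lon, lat = lat))
  out <- krige(nodes, aggregates, model, neighborhood = neighborhood)
  attr(out, "weights") <- NULL
  out
}

# IPCC calibrated likelihood bins over p in [0,1] (half-open, top closed)
IPCC_PHRASES <- data.frame(
  lower = c(0, 0.01, 0.10, 0.33, 0.66, 0.90, 0.99),
  upper = c(0.01, 0.10, 0.33, 0.66, 0.90, 0.99, 1),
  phrase = c("exceptionally unlikely", "very unlikely", "unlikely",
             "about as likely as not", "likely", "very likely",
             "virtually certain")
)

#' Probability of falling below a threshold, with calibrated phrasing
#'
#' Under the Gaussian prediction distribution of ordinary kriging,
#' `p = Phi((threshold - prediction) / sqrt(kriging variance))`; with zero
#' kriging variance the probability degenerates to 0 or 1 by direct
#' comparison. Probabilities are labelled with the IPCC calibrated
#' likelihood phrases.
#'
#' @param results data frame from [krige()]/[predict_grid()].
#' @param threshold policy threshold, ug/dL (default 70, the adequacy
#'   cutoff for women of reproductive age drawn fasting in the morning).
#' @param tol tolerance for slightly negative variances.
#' @return the input with `p_below` and `phrase` columns appended.
#' @export
exceedance_probability <- function(results, threshold = 70, tol = 1e-8) {
  kv <- results$kriging_variance
  if (any(kv < -tol)) stop("negative kriging variance")
  kv <- pmax(kv, 0)
  p <- ifelse(kv == 0,
              as.numeric(results$prediction < threshold),
              pnorm((threshold - results$prediction) / sqrt(kv)))
  results$p_below <- p
  idx <- findInterval(p, c(IPCC_PHRASES$lower, 1.0000001))
  idx[p >= 1] <- nrow(IPCC_PHRASES)
  results$phrase <- IPCC_PHRASES$phrase[idx]
  results
}

#' Order-statistic confidence interval for the median SSPE
#'
#' Distribution-free interval for the median of `n` standardised squared
#' errors under the chi-square(1 df) sampling model, from the binomial
#' order-statistic bounds. Provided as a diagnostic utility; model selection
#' uses the fixed published interval (0.355, 0.575).
#'
#' @param n number of sites.
#' @param level confidence level.
#' @return numeric `c(lower, upper)` on the SSPE scale.
#' @export
median_sspe_interval <- function(n, level = 0.95) {
  alpha <- (1 - level) / 2
  lo_k <- stats::qbinom(alpha, n, 0.5)
  hi_k <- stats::qbinom(1 - alpha, n, 0.5) + 1
  p_lo <- lo_k / n; p_hi <- min(hi_k, n) / n
  stats::qchisq(c(p_lo, p_hi), df = 1)
}
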