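test_that("great-circle distance matches closed forms and the sphere oracle", {
  expect_equal(great_circle_distance(c(10, 20), c(10, 20)), 0)
  # quarter great circle and antipode
  R <- 6371.0088
  expect_equal(great_circle_distance(c(0, 0), c(90, 0)), pi * R / 2,
               tolerance = 1e-9)
  expect_equal(great_circle_distance(c(0, 0), c(180, 0)), pi * R,
               tolerance = 1e-9)
  # independent oracle: Vincenty on a sphere of the same radius
  set.seed(3)
  p <- cbind(runif(20, -180, 179), runif(20, -80, 80))
  q <- cbind(runif(20, -180, 179), runif(20, -80, 80))
  oracle <- geosphere::distVincentySphere(p, q, r = R * 1000) / 1000
  expect_equal(great_circle_distance(p, q), oracle, tolerance = 1e-9)
  expect_error(great_circle_distance(c(0, 95), c(0, 0)), "latitude")
})

test_that("distance is symmetric and satisfies the triangle inequality", {
  set.seed(11)
  for (i in 1:50) {
    a <- c(runif(1, -180, 179), runif(1, -89, 89))
    b <- c(runif(1, -180, 179), runif(1, -89, 89))
    cc <- c(runif(1, -180, 179), runif(1, -89, 89))
    dab <- great_circle_distance(a, b)
    expect_equal(dab, great_circle_distance(b, a))
    expect_lte(dab, great_circle_distance(a, cc) +
                 great_circle_distance(cc, b) + 1e-9)
  }
  # matrix form agrees with the pairwise form
  xy <- cbind(runif(8, 30, 40), runif(8, 5, 10))
  m <- great_circle_matrix(xy)
  expect_equal(m[2, 7], great_circle_distance(xy[2, ], xy[7, ]))
  expect_equal(m, t(m))
})

test_that("bearings follow the compass conventions", {
  expect_equal(bearing(c(0, 0), c(0, 10)), 0)            # due north
  expect_equal(bearing(c(0, 0), c(10, 0)), 90)           # due east on equator
  expect_equal(bearing(c(0, 10), c(0, 0)), 180)
  # reversing an equatorial path flips the bearing by 180 degrees
  b1 <- bearing(c(5, 0), c(25, 0))
  b2 <- bearing(c(25, 0), c(5, 0))
  expect_equal((b1 - b2) %% 360, 180)
  expect_error(bearing(c(3, 4), c(3, 4)), "coincident")
})

test_that("Tukey outer fences flag only gross outliers", {
  vals <- c(1:9, 100)
  out <- tukey_outliers(vals)
  expect_equal(which(out$mask), 10L)
  # hinges of 1..9,100 are 3 and 8: outer fences at -12 and 23
  expect_equal(unname(out$fences), c(-12, 23))
  # clean symmetric sample: nothing flagged
  set.seed(2)
  expect_false(any(tukey_outliers(rnorm(200))$mask))
  # constant data: warning, nothing flagged
  expect_warning(res <- tukey_outliers(rep(5, 10)), "interquartile")
  expect_false(any(res$mask))
  expect_error(tukey_outliers(1:3), "at least 4")
})

test_that("variogram estimators match direct formula evaluation", {
  # single pair with values {0, 2}
  agg <- data.frame(ea_id = c("a", "b"), mean_zn = c(0, 2),
                    mean_lon = c(38, 38.05), mean_lat = c(8, 8))
  bins <- lag_bins(10, 20)
  gm <- estimate_variogram(agg, bins, "matheron")
  gc <- estimate_variogram(agg, bins, "cressie_hawkins")
  gd <- estimate_variogram(agg, bins, "dowd")
  expect_equal(gm$gamma[1], 2)                       # 4 / (2 * 1)
  expect_equal(gd$gamma[1], 2.198 * 4 / 2)           # 4.396
  expect_equal(gc$gamma[1], sqrt(2)^4 / (2 * (0.457 + 0.494)))
  expect_equal(gm$n_pairs[1], 1L)
  # constant field: all estimators zero in every non-empty bin
  aggc <- make_field_aggregates(15, list(c0 = 0, c1 = 0, a = 1))
  for (est in c("matheron", "cressie_hawkins", "dowd")) {
    v <- estimate_variogram(aggc, lag_bins(50, 600), est)
    expect_true(all(v$gamma[v$n_pairs > 0] == 0))
  }
})

test_that("binned estimates equal a brute-force pairwise computation", {
  set.seed(21)
  agg <- make_field_aggregates(18, list(c0 = 5, c1 = 20, a = 30))
  bins <- lag_bins(40, 480)
  # independent oracle: explicit double loop over all pairs
  brute <- function(estimator) {
    g <- rep(NA_real_, nrow(bins)); np <- integer(nrow(bins))
    diffs <- vector("list", nrow(bins))
    for (i in 1:17) for (j in (i + 1):18) {
      h <- geosphere::distVincentySphere(
        c(agg$mean_lon[i], agg$mean_lat[i]),
        c(agg$mean_lon[j], agg$mean_lat[j]), r = 6371008.8) / 1000
      b <- which(h >= bins$lower & h < bins$upper)
      if (length(b)) diffs[[b]] <- c(diffs[[b]], agg$mean_zn[i] - agg$mean_zn[j])
    }
    for (b in seq_len(nrow(bins))) {
      d <- diffs[[b]]; np[b] <- length(d)
      if (np[b] > 0) {
        g[b] <- switch(estimator,
          matheron = sum(d^2) / (2 * np[b]),
          cressie_hawkins = mean(sqrt(abs(d)))^4 /
            (2 * (0.457 + 0.494 / np[b])),
          dowd = 2.198 * median(abs(d))^2 / 2)
      }
    }
    list(gamma = g, n_pairs = np)
  }
  for (est in c("matheron", "cressie_hawkins", "dowd")) {
    v <- estimate_variogram(agg, bins, est)
    o <- brute(est)
    expect_equal(v$n_pairs, o$n_pairs)
    expect_equal(v$gamma, o$gamma, tolerance = 1e-9)
  }
})

test_that("Matheron estimates of iid noise converge to the variance", {
  set.seed(31)
  sigma2 <- 9
  bins <- lag_bins(50, 400)
  gh <- matrix(NA_real_, 200, nrow(bins))
  xy <- data.frame(ea_id = 1:120,
                   mean_lon = runif(120, 34, 44), mean_lat = runif(120, 4, 12))
  for (r in 1:200) {
    xy$mean_zn <- rnorm(120, 0, sqrt(sigma2))
    gh[r, ] <- estimate_variogram(xy, bins, "matheron")$gamma
  }
  expect_lt(max(abs(colMeans(gh) - sigma2) / sigma2), 0.05)
})

test_that("directional variograms partition pairs across sectors", {
  set.seed(41)
  agg <- make_field_aggregates(40, list(c0 = 5, c1 = 20, a = 30))
  bins <- lag_bins(50, 300)
  iso <- estimate_variogram(agg, bins, "matheron")
  dir <- estimate_variogram(agg, bins, "matheron",
                            direction_sectors = c(0, 45, 90, 135))
  expect_equal(sort(unique(dir$sector)), c(0, 45, 90, 135))
  by_bin <- tapply(dir$n_pairs, dir$mid, sum)
  expect_equal(as.vector(by_bin[as.character(iso$mid)]), iso$n_pairs)
})

test_that("WLS fitting recovers noise-free parameters and degrades gracefully", {
  bins <- lag_bins(10, 200)
  est <- bins
  est$n_pairs <- 200L
  est$gamma <- exponential_semivariance(bins$mid, REFERENCE_MODEL)
  class(est) <- c("zn_variogram", "data.frame")
  attr(est, "estimator") <- "matheron"
  fit <- fit_exponential_wls(est)
  expect_lt(abs(fit$c0 - 27.0) / 27.0, 1e-4)
  expect_lt(abs(fit$c1 - 39.62) / 39.62, 1e-4)
  expect_lt(abs(fit$a - 14.79) / 14.79, 1e-4)
  expect_equal(fit$effective_range, 3 * fit$a)
  # pure nugget: flat empirical variogram collapses c1 towards zero
  est$gamma <- rep(12, nrow(bins))
  expect_warning(fit0 <- fit_exponential_wls(est), "nugget")
  expect_lt(fit0$c1, 1e-4)
  expect_error(fit_exponential_wls(est[1:2, ]), "at least 3")
})

test_that("end-to-end refitting recovers the generating model in the median", {
  set.seed(55)
  cfg <- simulation_config(seed = 55)
  res <- t(replicate(30, {
    xy <- data.frame(ea_id = 1:315, mean_lon = runif(315, 33, 48),
                     mean_lat = runif(315, 3.5, 14.5))
    xy$mean_zn <- simulate_zn_field(
      data.frame(lon = xy$mean_lon, lat = xy$mean_lat), cfg)
    f <- fit_exponential_wls(estimate_variogram(xy, lag_bins(10, 200),
                                                "matheron"))
    c(sill = f$c0 + f$c1, a = f$a)
  }))
  expect_lt(abs(median(res[, "sill"]) - 66.62) / 66.62, 0.25)
  expect_gt(median(res[, "a"]), 14.79 / 2)
  expect_lt(median(res[, "a"]), 14.79 * 2)
})

test_that("EA aggregation averages values and coordinates", {
  r <- make_records(4, ea_id = c("A", "A", "B", "C"),
                    zn = c(50, 60, 70, 80),
                    lon = c(38, 38.01, 39, 40), lat = c(8, 8.01, 9, 10))
  agg <- aggregate_by_ea(r, value_col = "zn")
  expect_equal(nrow(agg), 3)
  a <- agg[agg$ea_id == "A", ]
  expect_equal(a$mean_zn, 55)
  expect_equal(a$mean_lon, 38.005)
  expect_equal(a$n_records, 2L)
  expect_equal(agg$mean_zn[agg$ea_id == "B"], 70)
  # wildly spread EA triggers the sanity warning
  r2 <- make_records(2, ea_id = "X", lon = c(38, 41), lat = c(8, 8))
  expect_warning(aggregate_by_ea(r2, value_col = "zn"), "spreads")
})
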