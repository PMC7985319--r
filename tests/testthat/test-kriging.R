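test_that("one-point kriging has the closed-form solution", {
  model <- REFERENCE_MODEL
  agg <- data.frame(ea_id = "a", mean_zn = 55, mean_lon = 38, mean_lat = 8)
  tgt <- c(38.5, 8.2)
  res <- krige(tgt, agg, model)
  h <- great_circle_distance(tgt, c(38, 8))
  g <- model$c0 + model$c1 * (1 - exp(-h / model$a))
  expect_equal(res$prediction, 55)
  expect_equal(res$kriging_variance, 2 * g, tolerance = 1e-10)
})

test_that("kriging is exact at data sites and weights sum to one", {
  set.seed(61)
  agg <- make_field_aggregates(40, REFERENCE_MODEL)
  model <- REFERENCE_MODEL
  # coincident target returns the datum with zero variance
  at_datum <- krige(c(agg$mean_lon[5], agg$mean_lat[5]), agg, model)
  expect_equal(at_datum$prediction, agg$mean_zn[5])
  expect_equal(at_datum$kriging_variance, 0)
  # unbiasedness: weights sum to 1 at every target, to 1e-10
  tgts <- cbind(runif(25, 36, 40), runif(25, 6, 10))
  res <- krige(tgts, agg, model)
  w <- attr(res, "weights")
  expect_true(all(abs(rowSums(w) - 1) < 1e-10))
  expect_true(all(res$kriging_variance >= 0))
  # duplicate data locations are an explicit error
  agg2 <- rbind(agg, agg[1, ])
  expect_error(krige(c(37, 7), agg2, model), "duplicate")
})

test_that("predictions revert to the mean far beyond the range", {
  set.seed(62)
  agg <- make_field_aggregates(30, REFERENCE_MODEL,
                               lon = c(38, 38.5), lat = c(8, 8.5))
  model <- REFERENCE_MODEL
  far <- krige(c(46, 13), agg, model)   # ~900 km away, >> 3a = 44 km
  near <- krige(c(38.25, 8.25), agg, model)
  # oracle: beyond the range the OK prediction tends to the GLS mean
  C <- model$c1 * exp(-great_circle_matrix(
    cbind(agg$mean_lon, agg$mean_lat)) / model$a) + diag(model$c0, 30)
  ones <- rep(1, 30)
  mu_gls <- sum(solve(C, agg$mean_zn)) / sum(solve(C, ones))
  expect_lt(abs(far$prediction - mu_gls), 1e-6)
  expect_gt(far$kriging_variance, model$c0 + model$c1)
  expect_lt(near$kriging_variance, far$kriging_variance)
})

test_that("nearest-k neighbourhood kriging approximates global kriging", {
  set.seed(63)
  agg <- make_field_aggregates(50, REFERENCE_MODEL)
  tgt <- c(38, 8)
  g <- krige(tgt, agg, REFERENCE_MODEL)
  k <- krige(tgt, agg, REFERENCE_MODEL, neighborhood = 25)
  expect_lt(abs(g$prediction - k$prediction), 1.5)
  expect_gte(k$kriging_variance + 1e-9, g$kriging_variance)
})

test_that("direct LOO shortcut equals explicit refitting", {
  set.seed(60)
  agg <- make_field_aggregates(25, REFERENCE_MODEL)
  fast <- cross_validate(agg, REFERENCE_MODEL, method = "direct")
  slow <- cross_validate(agg, REFERENCE_MODEL, method = "refit")
  expect_equal(fast$errors, slow$errors, tolerance = 1e-9)
  expect_equal(fast$kriging_variance, slow$kriging_variance,
               tolerance = 1e-9)
})

test_that("leave-one-out cross-validation is calibrated and diagnostic", {
  set.seed(64)
  agg <- make_field_aggregates(120, REFERENCE_MODEL)
  cv <- cross_validate(agg, REFERENCE_MODEL)
  expect_equal(length(cv$errors), 120)
  expect_true(all(cv$theta >= 0))
  expect_equal(cv$median_sspe, median(cv$errors^2 / cv$kriging_variance))
  # grossly inflated sill drives the median SSPE far below 0.455
  inflated <- list(c0 = 27 * 6, c1 = 39.62 * 6, a = 14.79)
  cv_bad <- cross_validate(agg, inflated)
  expect_lt(cv_bad$median_sspe, 0.355)
  expect_false(cv_bad$is_valid)
})

test_that("model selection prefers Matheron when valid, else closest to 0.455", {
  set.seed(80)
  agg <- make_field_aggregates(300, REFERENCE_MODEL)
  true_fit <- REFERENCE_MODEL
  bad_fit <- list(c0 = 27 * 8, c1 = 39.62 * 8, a = 14.79)
  # valid Matheron fit: robust alternatives never examined
  sel <- select_model(list(matheron = true_fit, dowd = bad_fit), agg)
  expect_equal(sel$chosen, "matheron")
  expect_true(sel$is_valid)
  expect_null(sel$trail$dowd)
  # invalid Matheron: the robust fit closest to 0.455 wins
  sel2 <- select_model(list(matheron = bad_fit, dowd = true_fit), agg)
  expect_equal(sel2$chosen, "dowd")
  expect_true(sel2$is_valid)
  expect_equal(length(sel2$trail), 2)
  # nothing valid: flagged, not silently accepted
  sel3 <- select_model(list(matheron = bad_fit,
                            cressie_hawkins = list(c0 = 270, c1 = 396,
                                                   a = 14.79)), agg)
  expect_false(sel3$is_valid)
  expect_error(select_model(list(dowd = true_fit), agg), "Matheron")
})

test_that("grid prediction is finite with spatially coherent variance", {
  set.seed(66)
  agg <- make_field_aggregates(40, REFERENCE_MODEL,
                               lon = c(37.8, 38.2), lat = c(7.8, 8.2))
  gs <- list(lon_min = 37, lon_max = 39, lat_min = 7, lat_max = 9, res = 0.2)
  grid <- predict_grid(agg, REFERENCE_MODEL, gs)
  expect_equal(nrow(grid), 11 * 11)
  expect_true(all(is.finite(grid$prediction)))
  expect_true(all(grid$kriging_variance >= 0))
  # variance near the data cloud is below variance far beyond 3a
  d_min <- apply(great_circle_matrix(rbind(
    as.matrix(grid[, c("lon", "lat")]),
    cbind(agg$mean_lon, agg$mean_lat)))[seq_len(nrow(grid)),
                                        -seq_len(nrow(grid))], 1, min)
  expect_lt(max(grid$kriging_variance[d_min < 5]),
            min(grid$kriging_variance[d_min > 3 * 14.79]))
  expect_error(predict_grid(agg, REFERENCE_MODEL, gs, node_cap = 10), "cap")
})

test_that("exceedance probabilities follow the Gaussian prediction law", {
  res <- data.frame(lon = 0, lat = 0,
                    prediction = c(70, 60, 50, 90),
                    kriging_variance = c(25, 25, 0, 0),
                    lagrange = 0)
  out <- exceedance_probability(res, threshold = 70)
  expect_equal(out$p_below[1], 0.5)
  expect_equal(out$phrase[1], "about as likely as not")
  expect_equal(out$p_below[2], pnorm(2), tolerance = 1e-12) # ~0.977
  expect_equal(out$phrase[2], "very likely")
  expect_equal(out$p_below[3], 1)   # degenerate, below threshold
  expect_equal(out$phrase[3], "virtually certain")
  expect_equal(out$p_below[4], 0)
  expect_equal(out$phrase[4], "exceptionally unlikely")
  expect_error(exceedance_probability(
    data.frame(prediction = 1, kriging_variance = -1)), "negative")
})

test_that("exceedance probability is monotone and phrases partition [0,1]", {
  pred <- seq(40, 100, by = 0.5)
  res <- data.frame(lon = 0, lat = 0, prediction = pred,
                    kriging_variance = 30, lagrange = 0)
  out <- exceedance_probability(res, threshold = 70)
  expect_true(all(diff(out$p_below) < 0))   # decreasing in the prediction
  expect_false(any(is.na(out$phrase)))
  # probabilities strictly inside each bin map to that bin's phrase
  p <- c(0, 0.005, 0.05, 0.2, 0.5, 0.8, 0.95, 0.995, 1)
  res2 <- data.frame(prediction = 70 - qnorm(p) * 5, kriging_variance = 25)
  out2 <- exceedance_probability(res2, threshold = 70)
  expect_equal(out2$phrase,
               c("exceptionally unlikely", "exceptionally unlikely",
                 "very unlikely", "unlikely", "about as likely as not",
                 "likely", "very likely", "virtually certain",
                 "virtually certain"))
})

test_that("median SSPE interval utility narrows with n", {
  i100 <- median_sspe_interval(100)
  i1000 <- median_sspe_interval(1000)
  expect_lt(i100[1], 0.455); expect_gt(i100[2], 0.455)
  expect_lt(diff(i1000), diff(i100))
})
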