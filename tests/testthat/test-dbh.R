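test_that("circle fit is exact on exact circles and translation-equivariant", {
  th <- seq(0, 2 * pi, length.out = 9)[-9]
  pts <- cbind(2 + 0.15 * cos(th), 3 + 0.15 * sin(th))
  f <- fit_circle_ls(pts)
  expect_equal(c(f$center_x_m, f$center_y_m, f$radius_m), c(2, 3, 0.15),
               tolerance = 1e-10)
  expect_lt(f$rms_m, 1e-12)
  f2 <- fit_circle_ls(pts + 100)
  expect_equal(f2$radius_m, f$radius_m, tolerance = 1e-10)
  expect_equal(c(f2$center_x_m, f2$center_y_m), c(102, 103),
               tolerance = 1e-8)
  expect_error(fit_circle_ls(cbind(1:5, 2 * (1:5))),
               class = "standscan_degenerate_fit_error")
  expect_error(fit_circle_ls(pts[1:2, ]),
               class = "standscan_degenerate_fit_error")
})

test_that("circle fit is nearly unbiased under radial noise", {
  set.seed(17)
  reps <- 500
  radii <- vapply(seq_len(reps), function(i) {
    th <- runif(24, 0, 2 * pi)
    r <- 0.15 + rnorm(24, 0, 0.005)
    fit_circle_ls(cbind(r * cos(th), r * sin(th)))$radius_m
  }, numeric(1))
  expect_lt(abs(mean(radii) - 0.15), 0.002)
})

test_that("DBH extraction recovers simulated stems and rejects clutter", {
  tr <- data.frame(tree_id = "a", x_m = 50, y_m = 50, height_m = 12,
                   dbh_cm = 30, crown_radius_m = 2.5)
  p <- tree_plot(tr)
  sl <- simulate_breast_height_slice(p, pts_per_stem = 48, radial_sd_m = 0,
                                     clutter_fraction = 0, seed = 2)
  f <- extract_dbh(sl, data.frame(x_m = 50, y_m = 50))
  expect_equal(f$dbh_cm, 30, tolerance = 0.1 / 30)

  # no slice points near the tree: absent, not an error
  expect_null(extract_dbh(sl, data.frame(x_m = 5, y_m = 5)))

  # pure branch clutter (dense, uniform in the crown, no stem circle) is
  # rejected by the rms/radius and radius quality caps; very sparse clutter
  # that happens to trace an arc is the residual failure mode the downstream
  # prediction-bound filter exists for
  rejected <- vapply(1:200, function(s) {
    set.seed(s)
    n <- 200
    rr <- 2.5 * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    clutter <- point_cloud(data.frame(x_m = 50 + rr * cos(th),
                                      y_m = 50 + rr * sin(th),
                                      z_m = runif(n, 1.32, 1.42)))
    is.null(extract_dbh(clutter, data.frame(x_m = 50, y_m = 50)))
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
})

test_that("power-model fitting recovers parameters and handles special cases", {
  # linear special case beta2 = 1
  h <- seq(2, 25, length.out = 30)
  pm_lin <- fit_power_model(h, 2.5 * h)
  expect_equal(pm_lin$beta2, 1, tolerance = 1e-6)

  # parameter-recovery Monte Carlo at the reported site-model means
  set.seed(5)
  b2 <- vapply(1:100, function(s) {
    hh <- runif(500, 2, 25)
    dd <- 4.29 * hh^0.68 + rnorm(500, 0, 1.2)
    fit_power_model(hh, dd)$beta2
  }, numeric(1))
  expect_lt(abs(mean(b2) - 0.68), 0.02)

  expect_error(fit_power_model(1:3, 1:3), class = "standscan_fit_error")
  expect_error(fit_power_model(c(-1, h), c(1, 2.5 * h)),
               class = "standscan_fit_error")
})

test_that("prediction intervals are centered, monotone in level, and calibrated", {
  set.seed(21)
  hh <- runif(300, 2, 25)
  dd <- 4.29 * hh^0.68 + rnorm(300, 0, 1.2)
  pm <- fit_power_model(hh, dd)
  pb90 <- prediction_interval(pm, c(5, 10, 20), level = 0.90)
  pb95 <- prediction_interval(pm, c(5, 10, 20), level = 0.95)
  expect_true(all(pb90$lo_cm < pb90$fit_cm & pb90$fit_cm < pb90$hi_cm))
  expect_true(all(pb95$hi_cm - pb95$lo_cm > pb90$hi_cm - pb90$lo_cm))

  # coverage of fresh observations: 90% +/- 2% over 1e4 draws
  hn <- runif(1e4, 2, 25)
  dn <- 4.29 * hn^0.68 + rnorm(1e4, 0, 1.2)
  pb <- prediction_interval(pm, hn, level = 0.90)
  expect_lt(abs(mean(dn >= pb$lo_cm & dn <= pb$hi_cm) - 0.90), 0.02)

  # Monte-Carlo propagation cross-checks the delta-method default
  mc <- prediction_interval(pm, c(5, 15), method = "monte_carlo",
                            n_sim = 20000, seed = 3)
  de <- prediction_interval(pm, c(5, 15))
  expect_equal(mc$lo_cm, de$lo_cm, tolerance = 0.02)
  expect_equal(mc$hi_cm, de$hi_cm, tolerance = 0.02)

  expect_error(prediction_interval(power_model(4, 0.7, 1, 2), 10),
               class = "standscan_insufficient_data_error")
})

test_that("prediction-bound filtering keeps curve points and drops gross outliers", {
  set.seed(33)
  hh <- runif(400, 2, 25)
  dd <- 4.29 * hh^0.68 + rnorm(400, 0, 1.2)
  pm <- fit_power_model(hh, dd)

  on_curve <- tibble::tibble(height_m = c(3, 8, 15),
                             dbh_cm = predict(pm, c(3, 8, 15)))
  expect_equal(nrow(filter_pairs_by_bounds(on_curve, pm)), 3)
  outlier <- tibble::tibble(height_m = 8, dbh_cm = 10 * predict(pm, 8))
  expect_equal(nrow(filter_pairs_by_bounds(outlier, pm)), 0)
  expect_equal(nrow(filter_pairs_by_bounds(on_curve[0, ], pm)), 0)

  # under the generating model ~90% of fresh noisy pairs survive
  keep_rate <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    h2 <- runif(300, 2, 25)
    d2 <- 4.29 * h2^0.68 + rnorm(300, 0, 1.2)
    nrow(filter_pairs_by_bounds(tibble::tibble(height_m = h2, dbh_cm = d2),
                                pm)) / 300
  }, numeric(1))
  expect_lt(abs(mean(keep_rate) - 0.90), 0.03)
})

test_that("imputation fills only missing DBH values and is idempotent", {
  pm <- power_model(4.29, 0.68, 1.2, 100)
  tr <- data.frame(tree_id = c("a", "b"), x_m = c(1, 2), y_m = c(1, 2),
                   height_m = c(10, 12), dbh_cm = c(25, NA),
                   dbh_origin = c("extracted", NA))
  p <- tree_plot(tr)
  p2 <- impute_missing_dbh(p, pm)
  expect_equal(p2$dbh_cm[1], 25)                       # untouched
  expect_equal(p2$dbh_cm[2], 4.29 * 12^0.68)
  expect_equal(p2$dbh_origin, c("extracted", "predicted"))
  expect_equal(as.data.frame(impute_missing_dbh(p2, pm)),
               as.data.frame(p2))                      # idempotent
  # all trees already extracted: no-op
  full <- tree_plot(transform(tr, dbh_cm = c(25, 30)))
  expect_equal(impute_missing_dbh(full, pm)$dbh_cm, c(25, 30))
  expect_error(impute_missing_dbh(p, NULL),
               class = "standscan_configuration_error")
})

test_that("the end-to-end DBH chain stays within the generating noise budget", {
  p <- random_plot(60, bounds = c(0, 0, 100, 100), hmin = 4, hmax = 22,
                   seed = 77)
  p <- assign_allometry(p, allometry_params(resid_sd_cm = 1.2), seed = 1)
  sl <- simulate_breast_height_slice(p, pts_per_stem = 48,
                                     radial_sd_m = 0.005,
                                     clutter_fraction = 0.1, seed = 2)
  regional <- power_model(4.29, 0.68, 6.2, 500)
  est <- suppressMessages(estimate_dbh(p, sl, regional))
  expect_true(all(!is.na(est$dbh_cm)))
  rmse <- sqrt(mean((est$dbh_cm - p$dbh_cm)^2))
  expect_lt(rmse, 3 * 1.2)
  expect_gt(attr(est, "extraction_rate"), 0)
})
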