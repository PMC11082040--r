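test_that("stand generation is deterministic in the seed and honors hard-core spacing", {
  ct <- treatment_archetype("CT")
  p1 <- generate_stem_map(ct, seed = 11)
  p2 <- generate_stem_map(ct, seed = 11)
  p3 <- generate_stem_map(ct, seed = 12)
  expect_equal(as.data.frame(p1), as.data.frame(p2))
  expect_false(isTRUE(all.equal(as.data.frame(p1), as.data.frame(p3))))
  # commercial thinning: minimum ~4.9 m spacing
  expect_gte(min(dist(cbind(p1$x_m, p1$y_m))), 4.9)

  empty <- treatment_archetype("custom", overstory_density = 0)
  expect_equal(nrow(generate_stem_map(empty, seed = 1)), 0)
  expect_error(
    generate_stem_map(treatment_archetype("custom",
                                          overstory_density = 2e5),
                      seed = 1),
    class = "standscan_parameter_error")
})

test_that("realized overstory density tracks the archetype target", {
  # 100 seeds, mean count within 3 Poisson SE of target
  for (name in c("FS_On", "CT")) {
    a <- treatment_archetype(name, understory_patch_fraction = 0)
    counts <- vapply(1:100, function(s) {
      nrow(generate_stem_map(a, seed = s))
    }, numeric(1))
    target <- a$overstory_density
    se_mean <- sqrt(target / 100)
    expect_lt(abs(mean(counts) - target), 3 * se_mean)
  }
})

test_that("allometry assignment follows the power law and refits exactly when noiseless", {
  p <- random_plot(60, seed = 4)
  ap <- allometry_params(resid_sd_cm = 0)
  p2 <- assign_allometry(p, ap, seed = 1)
  # direct evaluation: height 10 m -> 4.29 * 10^0.68
  ten <- assign_allometry(
    tree_plot(data.frame(tree_id = "x", x_m = 1, y_m = 1, height_m = 10)),
    ap, seed = 1)
  expect_equal(ten$dbh_cm, 4.29 * 10^0.68, tolerance = 1e-12)
  expect_equal(ten$dbh_cm, 20.5, tolerance = 0.01)
  # noiseless recovery to >= 6 significant digits
  pm <- fit_power_model(p2$height_m, p2$dbh_cm)
  expect_equal(pm$beta1, 4.29, tolerance = 1e-7)
  expect_equal(pm$beta2, 0.68, tolerance = 1e-7)
  expect_lt(pm$resid_se_cm, 1e-8)
  expect_true(all(p2$dbh_origin == "measured"))
  expect_true(all(p2$crown_radius_m >= 0.3))
  expect_error(assign_allometry(p, allometry_params(beta1 = -1)),
               class = "standscan_parameter_error")
})

test_that("rendered CHM matches the per-cell maximum of crown surfaces", {
  tr <- data.frame(tree_id = c("a", "b"), x_m = c(4.0, 6.0), y_m = c(5, 5),
                   height_m = c(12, 9), dbh_cm = NA,
                   crown_radius_m = c(3, 2.5))
  p <- tree_plot(tr, bounds = c(0, 0, 10, 10))
  ch <- render_chm(p, cell_size_m = 0.25, crown_exponent = 2)
  # brute-force per-cell max over the two crown surfaces
  cx <- 0.25 * (seq_len(40) - 0.5)
  expected <- matrix(0, 40, 40)
  for (r in 1:40) for (c in 1:40) {
    for (i in 1:2) {
      d <- sqrt((cx[c] - tr$x_m[i])^2 + (cx[r] - tr$y_m[i])^2)
      if (d <= tr$crown_radius_m[i]) {
        expected[r, c] <- max(expected[r, c],
                              tr$height_m[i] *
                                (1 - (d / tr$crown_radius_m[i])^2))
      }
    }
  }
  # stem cells additionally carry the exact apex height
  for (i in 1:2) {
    sr <- ceiling(tr$y_m[i] / 0.25); sc <- ceiling(tr$x_m[i] / 0.25)
    expected[sr, sc] <- max(expected[sr, sc], tr$height_m[i])
  }
  expect_equal(ch$values, expected, tolerance = 1e-12)
  expect_equal(max(ch$values), 12)                 # never exceeds tallest
  expect_true(all(render_chm(tree_plot(tr[0, ]))$values == 0))
})

test_that("breast-height slice geometry is exact when noiseless", {
  tr <- data.frame(tree_id = c("a", "b"), x_m = c(20, 60), y_m = c(20, 60),
                   height_m = c(12, 1.40), dbh_cm = c(30, 2),
                   crown_radius_m = c(2, 0.3))
  p <- tree_plot(tr)
  sl <- simulate_breast_height_slice(p, pts_per_stem = 24, radial_sd_m = 0,
                                     clutter_fraction = 0, seed = 5)
  # the 1.40 m tree is below the 1.42 m slice top: no points
  expect_equal(nrow(sl), 24)
  r <- sqrt((sl$x_m - 20)^2 + (sl$y_m - 20)^2)
  expect_equal(r, rep(0.15, 24), tolerance = 1e-12)
  expect_true(all(sl$z_m >= 1.32 & sl$z_m <= 1.42))
  # closed-form circle through the sampled points
  fit <- fit_circle_ls(cbind(sl$x_m, sl$y_m))
  expect_equal(fit$radius_m, 0.15, tolerance = 1e-9)
  expect_error(simulate_breast_height_slice(p, pts_per_stem = 2),
               class = "standscan_parameter_error")
})

test_that("zero perturbation is the identity and unit rates empty the plot", {
  p <- random_plot(40, seed = 9, dbh = TRUE, crown = TRUE)
  zero <- perturbation_params(
    fn_rate_by_class = c(understory = 0, intermediate = 0, overstory = 0),
    fp_rate_by_class = c(understory = 0, intermediate = 0, overstory = 0),
    xy_sd_m = 0, height_bias_m = 0, height_sd_m = 0, ingrowth_rate = 0)
  u <- perturb_to_uas(p, zero, seed = 1)
  expect_equal(u$tree_id, p$tree_id)
  expect_equal(u$x_m, p$x_m)
  expect_equal(u$height_m, p$height_m)
  expect_true(all(u$source == "uas"))

  gone <- perturbation_params(
    fn_rate_by_class = c(understory = 1, intermediate = 1, overstory = 1),
    fp_rate_by_class = c(understory = 0, intermediate = 0, overstory = 0))
  expect_equal(nrow(perturb_to_uas(p, gone, seed = 1)), 0)
  expect_error(perturbation_params(fn_rate_by_class = c(understory = 1.2,
                                                        intermediate = 0,
                                                        overstory = 0)),
               class = "standscan_parameter_error")
})

test_that("matching recovers the generating FP/FN rates on a sparse stand", {
  # 1000 trees spread over 16 ha so spurious trees rarely shadow deleted ones
  p <- random_plot(1000, bounds = c(0, 0, 400, 400), seed = 123)
  pp <- perturbation_params(
    fn_rate_by_class = c(understory = 0.168, intermediate = 0.168,
                         overstory = 0.168),
    fp_rate_by_class = c(understory = 0.295, intermediate = 0.295,
                         overstory = 0.295),
    xy_sd_m = 0.3, height_bias_m = 0, height_sd_m = 0.3)
  n_seeds <- 200
  fp <- fn <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    u <- perturb_to_uas(p, pp, seed = s)
    g <- glance(match_trees(u, p))
    fp[s] <- g$fp / (g$tp + g$fp)
    fn[s] <- g$fn / (g$tp + g$fn)
  }
  expect_lt(abs(mean(fp) - 0.295), 0.02)
  expect_lt(abs(mean(fn) - 0.168), 0.02)
})
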