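test_that("a tree list matches itself perfectly and empty lists degrade sanely", {
  p <- random_plot(50, seed = 2)
  u <- tree_plot(as.data.frame(p), bounds = plot_bounds(p), source = "uas")
  m <- match_trees(u, p)
  g <- glance(m)
  expect_equal(g$tp, 50)
  expect_equal(g$fp, 0)
  expect_equal(g$fn, 0)
  expect_equal(g$f_score, 1)

  m0 <- match_trees(u[0, ], p)
  expect_equal(nrow(m0$matches), 0)
  expect_equal(length(m0$false_negatives), 50)
  expect_error(match_trees(u, p, max_dist_m = 0),
               class = "standscan_parameter_error")
})

test_that("matching replays the greedy rule on random configurations", {
  for (s in 1:500) {
    set.seed(s)
    nf <- sample(3:12, 1)
    nu <- sample(3:12, 1)
    field <- tree_plot(data.frame(
      tree_id = sprintf("f%02d", 1:nf),
      x_m = runif(nf, 0, 15), y_m = runif(nf, 0, 15),
      height_m = runif(nf, 2, 12)), bounds = c(0, 0, 15, 15))
    uas <- tree_plot(data.frame(
      tree_id = sprintf("u%02d", 1:nu),
      x_m = runif(nu, 0, 15), y_m = runif(nu, 0, 15),
      height_m = runif(nu, 2, 12)), bounds = c(0, 0, 15, 15),
      source = "uas")
    m <- match_trees(uas, field)
    o <- oracle_greedy_match(uas, field)
    got <- m$matches[order(m$matches$uas_id), c("uas_id", "field_id")]
    want <- o[order(o$uas_id), ]
    expect_equal(as.data.frame(got), as.data.frame(want),
                 ignore_attr = TRUE)
    # count conservation invariants
    expect_equal(nrow(m$matches) + length(m$false_positives), nu)
    expect_equal(nrow(m$matches) + length(m$false_negatives), nf)
    expect_false(anyDuplicated(m$matches$field_id) > 0)
    expect_false(anyDuplicated(m$matches$uas_id) > 0)
  }
})

test_that("matching is invariant to input row order and monotone in tolerance", {
  p <- random_plot(40, bounds = c(0, 0, 30, 30), seed = 6)
  u <- perturb_to_uas(p, perturbation_params(
    fn_rate_by_class = c(understory = 0.2, intermediate = 0.2,
                         overstory = 0.2),
    fp_rate_by_class = c(understory = 0.2, intermediate = 0.2,
                         overstory = 0.2),
    xy_sd_m = 0.5, height_bias_m = 0, height_sd_m = 0.8), seed = 3)
  m1 <- match_trees(u, p)
  shuffle <- function(x) {
    restamped <- x[sample(nrow(x)), ]
    tree_plot(as.data.frame(restamped), bounds = plot_bounds(x),
              source = restamped$source[1])
  }
  set.seed(9)
  m2 <- match_trees(shuffle(u), shuffle(p))
  expect_equal(m1$matches[order(m1$matches$uas_id), ],
               m2$matches[order(m2$matches$uas_id), ], ignore_attr = TRUE)
  expect_setequal(m1$false_positives, m2$false_positives)

  # tightening the height gate never gains true positives
  tps <- vapply(c(2, 1.5, 1, 0.5, 0.25),
                function(tol) nrow(match_trees(u, p,
                                               max_height_err_m = tol)$matches),
                numeric(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("f_score matches the closed form and its conventions", {
  expect_equal(f_score(10, 0, 0), 1.0)
  expect_equal(f_score(0, 3, 5), 0)
  expect_equal(f_score(8, 2, 2), 0.8)
  expect_error(f_score(0, 0, 0), class = "standscan_domain_error")
  set.seed(4)
  for (i in 1:1000) {
    tp <- sample(0:50, 1); fp <- sample(0:50, 1); fn <- sample(0:50, 1)
    if (tp + fp + fn == 0) next
    want <- if (tp == 0) 0 else {
      p <- tp / (tp + fp); r <- tp / (tp + fn)
      2 * p * r / (p + r)
    }
    expect_equal(f_score(tp, fp, fn), want)
  }
})

test_that("detection rates class trees by the stated sides and boundaries", {
  field <- tree_plot(data.frame(
    tree_id = c("f1", "f2", "f3"),
    x_m = c(10, 20, 30), y_m = 10,
    height_m = c(4, 5.0, 16)))         # 5.0 m is intermediate (boundary)
  uas <- tree_plot(data.frame(
    tree_id = c("u1", "u2", "u3", "u4"),
    x_m = c(10, 20, 30, 50), y_m = 10,
    height_m = c(4.2, 5.1, 16.3, 3)), source = "uas")  # u4 spurious
  m <- match_trees(uas, field)
  r <- detection_rates(m, uas, field)
  expect_equal(r$tp_rate[r$class == "all"], 1)
  und <- r[r$class == "understory", ]
  expect_equal(und$tp, 1)      # f1 only: f2 at exactly 5.0 m is intermediate
  expect_equal(und$fp, 1)      # u4 classed by its own (uas) height
  inter <- r[r$class == "intermediate", ]
  expect_equal(inter$tp, 1)
  expect_equal(inter$fp, 0)
  # perfect match: F = 1 in every class
  mm <- match_trees(tree_plot(as.data.frame(field), source = "uas"), field)
  rr <- detection_rates(mm, field, field)
  expect_true(all(rr$f_score == 1))
  expect_true(all(rr$fp_rate == 0))
})

test_that("class-specific deletion rates are recovered from large plots", {
  p <- random_plot(1500, bounds = c(0, 0, 500, 500), hmin = 2, hmax = 25,
                   seed = 55)
  pp <- perturbation_params(
    fn_rate_by_class = c(understory = 0.5, intermediate = 0.1,
                         overstory = 0.05),
    fp_rate_by_class = c(understory = 0, intermediate = 0, overstory = 0),
    xy_sd_m = 0.2, height_bias_m = 0, height_sd_m = 0.2)
  fn_hat <- matrix(NA_real_, 30, 3)
  for (s in 1:30) {
    u <- perturb_to_uas(p, pp, seed = s)
    r <- detection_rates(match_trees(u, p), u, p)
    fn_hat[s, ] <- r$fn_rate[match(c("understory", "intermediate",
                                     "overstory"), r$class)]
  }
  est <- colMeans(fn_hat)
  expect_lt(abs(est[1] - 0.5), 0.03)
  expect_lt(abs(est[2] - 0.1), 0.03)
  expect_lt(abs(est[3] - 0.05), 0.03)
})

test_that("error summaries reproduce the mean/RMSE formulas per size class", {
  # constructed constant bias: ME = RMSE = 0.36
  field <- random_plot(30, seed = 12, dbh = TRUE)
  shifted <- as.data.frame(field)
  shifted$height_m <- shifted$height_m + 0.36
  uas <- tree_plot(shifted, bounds = plot_bounds(field), source = "uas")
  m <- match_trees(uas, field)
  es <- error_summary(m, uas, field)
  overall <- es[es$class == "all", ]
  expect_equal(overall$me_height_m, 0.36, tolerance = 1e-12)
  expect_equal(overall$rmse_height_m, 0.36, tolerance = 1e-12)

  # single pair with error -2
  f1 <- tree_plot(data.frame(tree_id = "f", x_m = 1, y_m = 1,
                             height_m = 10))
  u1 <- tree_plot(data.frame(tree_id = "u", x_m = 1, y_m = 1,
                             height_m = 8.5), source = "uas")
  es1 <- error_summary(match_trees(u1, f1), u1, f1)
  expect_equal(es1$me_height_m[es1$class == "all"], -1.5)
  expect_equal(es1$rmse_height_m[es1$class == "all"], 1.5)

  # random errors vs independently coded formulas, including DBH
  set.seed(31)
  noisy <- as.data.frame(field)
  dh <- rnorm(30, 0, 0.5)
  dd <- rnorm(30, 0, 2)
  noisy$height_m <- noisy$height_m + dh
  noisy$dbh_cm <- noisy$dbh_cm + dd
  u2 <- tree_plot(noisy, bounds = plot_bounds(field), source = "uas")
  m2 <- match_trees(u2, field)
  expect_equal(nrow(m2$matches), 30)
  es2 <- error_summary(m2, u2, field)
  all2 <- es2[es2$class == "all", ]
  key <- match(m2$matches$field_id, field$tree_id)
  errs_h <- m2$matches$height_error_m
  expect_equal(all2$me_height_m, sum(errs_h) / 30)
  expect_equal(all2$rmse_height_m, sqrt(sum(errs_h^2) / 30))
  expect_equal(all2$me_dbh_cm, mean(dd[key]))
  expect_equal(all2$rmse_dbh_cm, sqrt(mean(dd[key]^2)))
  expect_true(all(es2$rmse_height_m >= abs(es2$me_height_m) - 1e-12))
})
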