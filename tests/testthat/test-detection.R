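test_that("variable window radius is 0.2 x height", {
  expect_equal(variable_window_radius(10), 2.0)
  expect_equal(variable_window_radius(0), 0)
  expect_equal(variable_window_radius(1.37), 0.274)
  expect_error(variable_window_radius(-1), class = "standscan_domain_error")
})

test_that("point-to-raster CHM takes the per-cell maximum", {
  pc <- point_cloud(data.frame(x_m = c(5.05, 5.06, 2.0),
                               y_m = c(5.05, 5.06, 8.0),
                               z_m = c(12, 7, 3)))
  ch <- chm_from_points(pc, cell_size_m = 0.1, bounds = c(0, 0, 10, 10))
  expect_equal(sum(ch$values > 0), 2)
  expect_equal(ch$values[51, 51], 12)  # max of 12 and 7 in the same cell
  expect_equal(ch$values[80, 20], 3)

  # brute-force oracle on a random cloud
  set.seed(8)
  pc2 <- point_cloud(data.frame(x_m = runif(500, 0, 5),
                                y_m = runif(500, 0, 5),
                                z_m = runif(500, 0, 20)))
  ch2 <- chm_from_points(pc2, cell_size_m = 0.5, bounds = c(0, 0, 5, 5))
  expected <- matrix(0, 10, 10)
  for (k in seq_len(500)) {
    c <- min(10, max(1, ceiling(pc2$x_m[k] / 0.5)))
    r <- min(10, max(1, ceiling(pc2$y_m[k] / 0.5)))
    expected[r, c] <- max(expected[r, c], pc2$z_m[k])
  }
  expect_equal(ch2$values, expected)
  expect_error(chm_from_points(pc, bounds = c(200, 200, 300, 300)),
               class = "standscan_empty_input_error")
})

test_that("treetop detection equals the brute-force local-max predicate", {
  # single rendered cone: exactly one treetop at the apex
  tr <- data.frame(tree_id = "a", x_m = 5, y_m = 5, height_m = 15,
                   crown_radius_m = 3)
  ch <- render_chm(tree_plot(tr, bounds = c(0, 0, 10, 10)),
                   cell_size_m = 0.25)
  tops <- detect_treetops(ch)
  expect_equal(nrow(tops), 1)
  expect_equal(tops$height_m, 15)
  expect_equal(c(tops$x_m, tops$y_m), c(4.875, 4.875))  # stem cell center

  # degenerate plateau: uniform CHM yields one treetop, first in scan order
  flat <- chm(matrix(10, 30, 30), cell_size_m = 0.25)
  ft <- detect_treetops(flat)
  expect_equal(nrow(ft), 1)
  expect_equal(c(ft$x_m, ft$y_m), c(0.125, 0.125))

  # oracle equivalence across random multi-tree CHMs
  for (s in 1:8) {
    p <- random_plot(12, bounds = c(0, 0, 20, 20), hmin = 2, hmax = 15,
                     seed = 100 + s, crown = TRUE)
    ch <- render_chm(p, cell_size_m = 0.5)
    got <- treetops_to_cells(detect_treetops(ch), ch)
    want <- oracle_treetops(ch)
    expect_equal(cells_key(got), cells_key(want))
  }
})

test_that("treetop count is monotone non-increasing in the height threshold", {
  p <- random_plot(25, bounds = c(0, 0, 50, 50), seed = 31, crown = TRUE)
  ch <- render_chm(p, cell_size_m = 0.5)
  counts <- vapply(c(1.37, 3, 6, 10, 15, 20),
                   function(h) nrow(detect_treetops(ch, h)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("well-separated stands are recovered perfectly", {
  # spacing > 2 * 0.2 * max height guarantees exclusive windows
  g <- expand.grid(x = seq(10, 90, by = 12), y = seq(10, 90, by = 12))
  tr <- data.frame(tree_id = sprintf("t%02d", seq_len(nrow(g))),
                   x_m = g$x, y_m = g$y, height_m = 18,
                   crown_radius_m = 2.5)
  p <- tree_plot(tr)
  tops <- detect_treetops(render_chm(p))
  m <- match_trees(tree_plot(tops, source = "uas"), p)
  g2 <- glance(m)
  expect_equal(g2$recall, 1)
  expect_equal(g2$fp, 0)
})

test_that("crown segmentation produces one labeled region per treetop", {
  tr <- data.frame(tree_id = "a", x_m = 10, y_m = 10, height_m = 25,
                   crown_radius_m = 3)
  p <- tree_plot(tr, bounds = c(0, 0, 20, 20))
  ch <- render_chm(p)
  tops <- detect_treetops(ch)
  seg <- segment_crowns(ch, tops)
  # isolated crown: segment area close to the disk where surface >= 1.37 m
  expect_equal(seg$crown_area_m2$crown_area_m2, pi * 9, tolerance = 0.1)
  # labels partition the crown mask
  mask <- ch$values >= 1.37
  expect_equal(sum(seg$labels > 0), sum(mask))
  expect_equal(sum(seg$crown_area_m2$crown_area_m2),
               sum(seg$labels > 0) * 0.1^2)

  # two equal touching crowns split symmetrically
  tr2 <- data.frame(tree_id = c("a", "b"), x_m = c(8, 13), y_m = c(10, 10),
                    height_m = 20, crown_radius_m = 3)
  p2 <- tree_plot(tr2, bounds = c(0, 0, 20, 20))
  ch2 <- render_chm(p2)
  tops2 <- detect_treetops(ch2)
  expect_equal(nrow(tops2), 2)
  seg2 <- segment_crowns(ch2, tops2)
  a <- seg2$crown_area_m2$crown_area_m2
  expect_lt(abs(a[1] - a[2]) / mean(a), 0.05)

  # zero treetops -> all-zero labels; stray treetop -> consistency error
  seg0 <- segment_crowns(ch, tops[0, ])
  expect_true(all(seg0$labels == 0))
  bad <- tops
  bad$x_m <- 500
  expect_error(segment_crowns(ch, bad),
               class = "standscan_consistency_error")
})

test_that("canopy cover counts the cells at or above the threshold", {
  expect_equal(canopy_cover_from_chm(chm(matrix(0, 10, 10))), 0)
  expect_equal(canopy_cover_from_chm(chm(matrix(10, 10, 10))), 1)
  half <- matrix(c(rep(0, 50), rep(5, 50)), 10, 10)
  expect_equal(canopy_cover_from_chm(chm(half)), 0.5)
})
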