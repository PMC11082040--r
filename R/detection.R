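# Treetop detection, crown segmentation, and cover from canopy height models.

#' Rasterize a point cloud to a canopy height model
#'
#' Point-to-raster gridding: each cell takes the maximum point height falling
#' in it; cells containing no points are 0 (with photogrammetric densities of
#' thousands of points per square meter, empty cells are negligible; sparse
#' synthetic clouds simply read as ground).
#'
#' @param cloud A [point_cloud()].
#' @param cell_size_m Cell size (m), default 0.10.
#' @param bounds Rectangle `c(xmin, ymin, xmax, ymax)` to grid over.
#' @return A [chm()].
#' @export
chm_from_points <- function(cloud, cell_size_m = 0.1,
                            bounds = c(0, 0, 100, 100)) {
  check_positive_scalar(cell_size_m, "cell_size_m")
  nx <- max(1L, round((bounds[3] - bounds[1]) / cell_size_m))
  ny <- max(1L, round((bounds[4] - bounds[2]) / cell_size_m))
  ix <- pmax(1L, ceiling((cloud$x_m - bounds[1]) / cell_size_m))
  iy <- pmax(1L, ceiling((cloud$y_m - bounds[2]) / cell_size_m))
  ok <- cloud$x_m >= bounds[1] & cloud$x_m <= bounds[3] &
    cloud$y_m >= bounds[2] & cloud$y_m <= bounds[4]
  ix <- pmin(ix[ok], nx); iy <- pmin(iy[ok], ny)
  if (length(ix) == 0) {
    ss_abort("no points fall inside the requested bounds.",
             "standscan_empty_input_error")
  }
  z <- cloud$z_m[ok]
  vals <- matrix(0, nrow = ny, ncol = nx)
  lin <- (ix - 1L) * ny + iy
  mx <- tapply(z, lin, max)
  vals[as.integer(names(mx))] <- pmax(0, mx)
  chm(vals, origin = bounds[1:2], cell_size_m = cell_size_m)
}

#' Variable-window search radius
#'
#' The local-maximum search radius scales with canopy height:
#' `radius_m = 0.2 * height_m`.
#'
#' @param height_m Canopy height (m), non-negative.
#' @return Radius in meters.
#' @export
#' @examples
#' variable_window_radius(10)  # 2 m
variable_window_radius <- function(height_m) {
  if (any(height_m < 0)) {
    ss_abort("height must be non-negative.", "standscan_domain_error")
  }
  0.2 * height_m
}

#' Detect treetops with a variable-window local-maximum filter
#'
#' A cell is a treetop iff its value is at least `min_height_m` and is >=
#' every other cell value within Euclidean distance
#' [variable_window_radius()] of its center (the window is a circle in world
#' distance, not a pixel square). Plateaus — connected regions of equal
#' passing cells — yield a single treetop at the smallest `(row, col)` in
#' grid scan order, so results are reproducible on rendered surfaces with
#' flat apexes. No smoothing or pit-filling is applied; `NA` cells are
#' treated as ground (0).
#'
#' @param chm A [chm()].
#' @param min_height_m Minimum tree height (default 1.37 m).
#' @return A tibble of class `detected_trees`: `tree_id`, `x_m`, `y_m`,
#'   `height_m`, sorted by descending height.
#' @export
detect_treetops <- function(chm, min_height_m = 1.37) {
  stopifnot(inherits(chm, "chm"))
  v <- chm$values
  v[!is.finite(v)] <- 0
  ny <- nrow(v); nx <- ncol(v)
  cs <- chm$cell_size_m
  # stage 1: cheap 3x3 prefilter; an adjacent higher neighbor only disqualifies
  # a cell when it actually falls inside that cell's circular window, so short
  # trees (radius < cell size) are never pruned here
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- v
  rad_all <- variable_window_radius(pmax(v, 0))
  is_max <- v >= min_height_m
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    neigh_dist <- cs * sqrt(dr^2 + dc^2)
    ge_neigh <- v >= pad[(2 + dr):(ny + 1 + dr), (2 + dc):(nx + 1 + dc)]
    is_max <- is_max & (ge_neigh | rad_all < neigh_dist)
  }
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(empty_detected())
  }
  # stage 2: full circular-window check at each candidate
  pass <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    r <- cand[k, 1]; c <- cand[k, 2]
    h <- v[r, c]
    rad <- variable_window_radius(h)
    kc <- floor(rad / cs + 1e-9)
    rr <- max(1, r - kc):min(ny, r + kc)
    cc <- max(1, c - kc):min(nx, c + kc)
    d2 <- outer((rr - r)^2, (cc - c)^2, `+`) * cs^2
    w <- v[rr, cc, drop = FALSE]
    pass[k] <- h >= max(w[d2 <= rad^2 + 1e-12])
  }
  cand <- cand[pass, , drop = FALSE]
  if (nrow(cand) == 0) return(empty_detected())
  keep <- dedupe_plateaus(cand, v)
  rows <- unname(cand[keep, 1]); cols <- unname(cand[keep, 2])
  heights <- v[cbind(rows, cols)]
  ord <- order(-heights, rows, cols)
  out <- tibble(
    tree_id = sprintf("d%04d", seq_along(ord)),
    x_m = chm$origin[1] + (cols[ord] - 0.5) * cs,
    y_m = chm$origin[2] + (rows[ord] - 0.5) * cs,
    height_m = heights[ord])
  structure(out, class = c("detected_trees", class(tibble())))
}

empty_detected <- function() {
  structure(tibble(tree_id = character(0), x_m = numeric(0),
                   y_m = numeric(0), height_m = numeric(0)),
            class = c("detected_trees", class(tibble())))
}

# collapse 8-connected equal-valued passing cells to the smallest (row, col);
# returns indices into `cand` to keep
dedupe_plateaus <- function(cand, v) {
  n <- nrow(cand)
  if (n == 1) return(1L)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  key <- cand[, 1] + 1i * cand[, 2]
  idx <- setNames(seq_len(n), paste(cand[, 1], cand[, 2]))
  for (k in seq_len(n)) {
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      j <- idx[paste(cand[k, 1] + dr, cand[k, 2] + dc)]
      if (!is.na(j) &&
          v[cand[k, 1], cand[k, 2]] == v[cand[j, 1], cand[j, 2]]) {
        ri <- find(k); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  keep <- logical(n)
  for (g in unique(roots)) {
    members <- which(roots == g)
    ord <- members[order(cand[members, 1], cand[members, 2])]
    keep[ord[1]] <- TRUE
  }
  which(keep)
}

#' Segment tree crowns by marker-controlled watershed
#'
#' Grows crown segments outward from the detected treetops over the inverted
#' canopy surface, restricted to cells at or above `crown_min_height_m`
#' (seeded watershed via `EBImage::propagate()`). Every treetop's own cell
#' carries its label; crown area is the labeled cell count times the cell
#' area.
#'
#' @param chm The [chm()] the treetops were detected on.
#' @param treetops A `detected_trees` tibble from [detect_treetops()].
#' @param crown_min_height_m Minimum canopy height counted as crown
#'   (default 1.37 m).
#' @return A list of class `crown_segmentation`: `labels` (integer matrix
#'   aligned to the CHM; 0 = non-crown) and `crown_area_m2` (tibble
#'   `tree_id`, `crown_area_m2`).
#' @export
segment_crowns <- function(chm, treetops, crown_min_height_m = 1.37) {
  stopifnot(inherits(chm, "chm"))
  v <- chm$values
  v[!is.finite(v)] <- 0
  ny <- nrow(v); nx <- ncol(v)
  cs <- chm$cell_size_m
  labels <- matrix(0L, ny, nx)
  if (nrow(treetops) == 0) {
    return(structure(list(labels = labels,
                          crown_area_m2 = tibble(tree_id = character(0),
                                                 crown_area_m2 = numeric(0))),
                     class = "crown_segmentation"))
  }
  col <- ceiling((treetops$x_m - chm$origin[1]) / cs)
  row <- ceiling((treetops$y_m - chm$origin[2]) / cs)
  if (any(col < 1 | col > nx | row < 1 | row > ny)) {
    ss_abort("treetop falls outside the CHM grid.",
             "standscan_consistency_error")
  }
  seeds <- matrix(0L, ny, nx)
  seeds[cbind(row, col)] <- seq_len(nrow(treetops))
  mask <- v >= crown_min_height_m
  mask[cbind(row, col)] <- TRUE  # a treetop cell is always crown
  inv <- max(v) - v              # watershed relief: treetops are basins
  lab <- EBImage::propagate(inv, seeds, mask = mask)
  labels <- matrix(as.integer(round(lab)), ny, nx)
  counts <- tabulate(labels[labels > 0], nbins = nrow(treetops))
  structure(list(labels = labels,
                 crown_area_m2 = tibble(tree_id = treetops$tree_id,
                                        crown_area_m2 = counts * cs^2)),
            class = "crown_segmentation")
}

#' Canopy cover from a canopy height model
#'
#' The fraction of CHM cells at or above `crown_min_height_m`; `NA` cells
#' count as ground.
#'
#' @inheritParams segment_crowns
#' @return Fraction in `[0, 1]`.
#' @export
canopy_cover_from_chm <- function(chm, crown_min_height_m = 1.37) {
  stopifnot(inherits(chm, "chm"))
  v <- chm$values
  v[!is.finite(v)] <- 0
  mean(v >= crown_min_height_m)
}
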