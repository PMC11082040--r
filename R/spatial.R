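# Individuals, clumps, and openings: spatial-structure characterization of a
# stand at the interlocking-crown distance.

#' Assign trees to clumps at an inter-stem distance threshold
#'
#' Two trees belong to the same clump when they are connected by a chain of
#' stems each at most `eps_m` apart (6 m by default — the distance at which
#' ~3 m crown radii can interlock). This is DBSCAN with a neighborhood count
#' of 2, i.e., the connected components of the distance-threshold graph;
#' trees farther than `eps_m` from all others are singleton clumps
#' ("individuals"). Clump ids are deterministic: clumps are numbered by
#' their smallest member `tree_id`.
#'
#' @param plot A [tree_plot()].
#' @param eps_m Linking distance (m), default 6.0.
#' @return A tibble of class `clump_assignment`: `tree_id`, `clump_id`,
#'   `clump_size`.
#' @export
assign_clumps <- function(plot, eps_m = 6.0) {
  check_positive_scalar(eps_m, "eps_m")
  n <- nrow(plot)
  if (n == 0) {
    return(structure(tibble(tree_id = character(0), clump_id = integer(0),
                            clump_size = integer(0)),
                     class = c("clump_assignment", class(tibble()))))
  }
  d <- as.matrix(dist(cbind(plot$x_m, plot$y_m)))
  adj <- d <= eps_m
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # renumber deterministically by smallest member id within each component
  first_id <- tapply(plot$tree_id, comp, min)
  new_id <- setNames(rank(first_id, ties.method = "first"), names(first_id))
  clump_id <- as.integer(new_id[as.character(comp)])
  sizes <- tabulate(clump_id)
  structure(tibble(tree_id = plot$tree_id, clump_id = clump_id,
                   clump_size = sizes[clump_id]),
            class = c("clump_assignment", class(tibble())))
}

#' Clump size class label
#'
#' `1` is an individual; larger clumps fall in the classes 2-4, 5-9, 10-15,
#' and >15 trees.
#'
#' @param size Integer clump size(s), >= 1.
#' @return Factor with levels `individual`, `2-4`, `5-9`, `10-15`, `>15`.
#' @export
clump_class <- function(size) {
  if (any(size < 1)) {
    ss_abort("clump size must be >= 1.", "standscan_domain_error")
  }
  cut(size, breaks = c(0, 1, 4, 9, 15, Inf),
      labels = c("individual", "2-4", "5-9", "10-15", ">15"))
}

#' Per-clump and per-class structure metrics
#'
#' For every clump: percent of stand basal area, coefficient of variation of
#' member heights (sample SD / mean, in percent; clumps of >= 2 only), and
#' dissolved crown area (union of member crown disks, rasterized at 0.10 m).
#' The class summary reports, per clump size class, the clump count and the
#' mean and SD of each per-clump value.
#'
#' @param plot A [tree_plot()] with `dbh_cm`, `height_m`, `crown_radius_m`.
#' @param assignment A [assign_clumps()] result for `plot`.
#' @param cell_size_m Rasterization grain for crown-area dissolves.
#' @return A list of class `clump_metrics`: `per_clump` (tibble `clump_id`,
#'   `size`, `class`, `ba_pct`, `height_cv_pct`, `crown_area_m2`) and
#'   `by_class` (tibble `class`, `n_clumps`, means and SDs).
#' @export
clump_metrics <- function(plot, assignment, cell_size_m = 0.1) {
  if (nrow(plot) > 0 && (anyNA(plot$dbh_cm) || anyNA(plot$height_m))) {
    ss_abort("clump metrics need complete heights and DBH.",
             "standscan_accounting_error")
  }
  df <- left_join(as_tibble(plot), as_tibble(assignment), by = "tree_id")
  stand_ba <- sum(pi * (df$dbh_cm / 200)^2)
  per <- df %>%
    group_by(.data$clump_id) %>%
    summarise(
      size = dplyr::n(),
      ba_pct = 100 * sum(pi * (.data$dbh_cm / 200)^2) / stand_ba,
      height_cv_pct = if (dplyr::n() >= 2) {
        100 * sd(.data$height_m) / mean(.data$height_m)
      } else NA_real_,
      crown_area_m2 = clump_crown_area(.data$x_m, .data$y_m,
                                       .data$crown_radius_m, cell_size_m),
      .groups = "drop") %>%
    mutate(class = clump_class(.data$size)) %>%
    select("clump_id", "size", "class", "ba_pct", "height_cv_pct",
           "crown_area_m2")
  by_class <- per %>%
    group_by(.data$class, .drop = FALSE) %>%
    summarise(
      n_clumps = dplyr::n(),
      mean_ba_pct = mean(.data$ba_pct),
      sd_ba_pct = sd(.data$ba_pct),
      mean_height_cv_pct = mean(.data$height_cv_pct),
      sd_height_cv_pct = sd(.data$height_cv_pct),
      mean_crown_area_m2 = mean(.data$crown_area_m2),
      sd_crown_area_m2 = sd(.data$crown_area_m2),
      .groups = "drop")
  structure(list(per_clump = per, by_class = by_class),
            class = "clump_metrics")
}

# dissolved area of one clump's crown disks (bounding-box rasterization)
clump_crown_area <- function(x, y, r, cell_size_m) {
  if (anyNA(r)) {
    ss_abort("clump crown area needs crown radii for all members.",
             "standscan_accounting_error")
  }
  b <- c(min(x - r) - cell_size_m, min(y - r) - cell_size_m,
         max(x + r) + cell_size_m, max(y + r) + cell_size_m)
  mask <- rasterize_disks(x, y, r, b, cell_size_m)
  sum(mask) * cell_size_m^2
}

#' Distribution of plot area by distance to the nearest tree
#'
#' Evaluates the distance from every cell center of a regular grid (1.0 m by
#' default) to the nearest tree stem and reports the proportion of plot area
#' in consecutive `band_m`-wide distance bands: `[0,3)`, `[3,6)`, `[6,9)`,
#' `[9,12)`, `[12,Inf)` at the defaults. An empty plot has all its area in
#' the top band.
#'
#' @param plot A [tree_plot()].
#' @param grid_m Grid spacing (m), default 1.0.
#' @param band_m Band width (m), default 3.0.
#' @param n_bands Number of bands (the last is open-ended), default 5.
#' @return A tibble of class `opening_distribution`: `band`, `lo_m`, `hi_m`,
#'   `proportion` (sums to 1).
#' @export
opening_distribution <- function(plot, grid_m = 1.0, band_m = 3.0,
                                 n_bands = 5) {
  check_positive_scalar(grid_m, "grid_m")
  check_positive_scalar(band_m, "band_m")
  b <- plot_bounds(plot)
  gx <- seq(b[1] + grid_m / 2, b[3], by = grid_m)
  gy <- seq(b[2] + grid_m / 2, b[4], by = grid_m)
  npts <- length(gx) * length(gy)
  if (nrow(plot) == 0) {
    d <- rep(Inf, npts)
  } else {
    pts_x <- rep(gx, times = length(gy))
    pts_y <- rep(gy, each = length(gx))
    d2 <- rep(Inf, npts)
    for (i in seq_len(nrow(plot))) {
      d2 <- pmin(d2, (pts_x - plot$x_m[i])^2 + (pts_y - plot$y_m[i])^2)
    }
    d <- sqrt(d2)
  }
  lo <- (seq_len(n_bands) - 1) * band_m
  hi <- c(lo[-1], Inf)
  counts <- vapply(seq_len(n_bands), function(k) {
    if (k == n_bands) sum(d >= lo[k]) else sum(d >= lo[k] & d < hi[k])
  }, numeric(1))
  structure(tibble(
    band = c(sprintf("[%g,%g)", lo[-n_bands], hi[-n_bands]),
             sprintf(">=%g", lo[n_bands])),
    lo_m = lo, hi_m = hi, proportion = counts / npts),
    class = c("opening_distribution", class(tibble())))
}
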