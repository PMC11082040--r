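#' Stand-level summary of a tree list
#'
#' Computes the classic density and size metrics of a stand: trees per
#' hectare (TPH), TPH of trees taller than 5 m, basal area (m2/ha),
#' quadratic mean diameter (QMD, cm), and — when supplied — canopy cover.
#'
#' @param plot A [tree_plot()]; every tree must carry `dbh_cm`.
#' @param area_ha Plot area in hectares; defaults to the area of the plot's
#'   bounds.
#' @param cover Optional canopy-cover fraction in `[0, 1]` (e.g., from
#'   [canopy_cover_from_chm()] or [dissolved_crown_cover()]).
#' @return A one-row tibble: `tph`, `tph_gt5`, `ba_m2ha`, `qmd_cm`,
#'   `cover_frac`. `qmd_cm` is `NA` for an empty plot.
#' @export
#' @examples
#' p <- tree_plot(data.frame(tree_id = 1:2, x_m = c(10, 20), y_m = c(10, 20),
#'                           height_m = c(8, 15), dbh_cm = c(10, 30)))
#' stand_summary(p)
stand_summary <- function(plot, area_ha = NULL, cover = NA_real_) {
  area_ha <- area_ha %||% plot_area_ha(plot)
  check_positive_scalar(area_ha, "area_ha")
  n <- nrow(plot)
  if (n > 0 && anyNA(plot$dbh_cm)) {
    ss_abort(paste0("trees without DBH: ",
                    paste(plot$tree_id[is.na(plot$dbh_cm)], collapse = ", ")),
             "standscan_accounting_error")
  }
  ba <- if (n) sum(pi * (plot$dbh_cm / 200)^2) / area_ha else 0
  tibble(
    tph = n / area_ha,
    tph_gt5 = sum(plot$height_m > 5) / area_ha,
    ba_m2ha = ba,
    qmd_cm = if (n) sqrt(sum(plot$dbh_cm^2) / n) else NA_real_,
    cover_frac = if (is.numeric(cover)) as.numeric(cover)[1] else NA_real_
  )
}

#' Quadratic mean diameter from basal area and density
#'
#' Inverts the basal-area identity: `qmd_cm = 200 * sqrt(ba / (pi * tph))`,
#' the diameter of the tree of mean basal area.
#'
#' @param ba_m2ha Basal area (m2/ha).
#' @param tph Trees per hectare.
#' @return QMD in cm.
#' @export
#' @examples
#' qmd_from_ba_tph(13.9, 159)  # ~33.4 cm
qmd_from_ba_tph <- function(ba_m2ha, tph) {
  if (any(ba_m2ha <= 0) || any(tph <= 0)) {
    ss_abort("ba_m2ha and tph must be positive.", "standscan_domain_error")
  }
  200 * sqrt(ba_m2ha / (pi * tph))
}

#' Canopy cover from dissolved crown disks
#'
#' Models each tree crown as a disk of its crown radius, dissolves the disks
#' (union, so overlap counts once), clips to the plot bounds, and reports the
#' covered fraction. The union is computed by rasterizing at `cell_size_m`
#' (default 0.10 m), matching the pixel-based cover definition used for
#' canopy height models.
#'
#' @param plot A [tree_plot()] whose trees carry `crown_radius_m`.
#' @param bounds Rectangle `c(xmin, ymin, xmax, ymax)`; defaults to the
#'   plot's bounds.
#' @param cell_size_m Rasterization grain (m).
#' @return Covered fraction in `[0, 1]`.
#' @export
dissolved_crown_cover <- function(plot, bounds = NULL, cell_size_m = 0.1) {
  bounds <- bounds %||% plot_bounds(plot)
  check_positive_scalar(cell_size_m, "cell_size_m")
  if (nrow(plot) == 0) return(0)
  if (anyNA(plot$crown_radius_m)) {
    ss_abort(paste0("trees without crown radius: ",
                    paste(plot$tree_id[is.na(plot$crown_radius_m)],
                          collapse = ", ")),
             "standscan_accounting_error")
  }
  mask <- rasterize_disks(plot$x_m, plot$y_m, plot$crown_radius_m,
                          bounds, cell_size_m)
  sum(mask) / length(mask)
}

# logical matrix (rows = y) marking cells whose center lies in any disk
rasterize_disks <- function(x, y, r, bounds, cell_size_m) {
  nx <- max(1L, round((bounds[3] - bounds[1]) / cell_size_m))
  ny <- max(1L, round((bounds[4] - bounds[2]) / cell_size_m))
  cx <- bounds[1] + (seq_len(nx) - 0.5) * cell_size_m
  cy <- bounds[2] + (seq_len(ny) - 0.5) * cell_size_m
  mask <- matrix(FALSE, nrow = ny, ncol = nx)
  for (i in seq_along(x)) {
    if (r[i] <= 0) next
    jx <- which(abs(cx - x[i]) <= r[i])
    jy <- which(abs(cy - y[i]) <= r[i])
    if (!length(jx) || !length(jy)) next
    dx2 <- (cx[jx] - x[i])^2
    dy2 <- (cy[jy] - y[i])^2
    hit <- outer(dy2, dx2, `+`) <= r[i]^2
    mask[jy, jx] <- mask[jy, jx] | hit
  }
  mask
}

#' Paired stem-map vs drone stand estimates for eleven 1-ha plots
#'
#' Loads the packaged comparison table: eleven 100 m x 100 m ponderosa
#' pine plots under four thinning treatments (SGR small-group retention,
#' CT commercial thinning, FS-On and FS-Off free selection), each with
#' paired field stem-map and drone-derived estimates of QMD (cm), trees per
#' hectare (all trees and trees > 5 m), basal area (m2/ha), and canopy
#' cover (%).
#'
#' @return An 11-row tibble with columns `plot`, `treatment`, and
#'   `<metric>_stem` / `<metric>_uas` pairs.
#' @export
stand_comparison <- function() {
  path <- system.file("extdata", "stand_comparison.csv",
                      package = "standscan")
  if (path == "" || !file.exists(path)) {
    ss_abort("packaged stand comparison table not found.",
             "standscan_packaging_error")
  }
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Paired-plot error statistics for stand metrics
#'
#' For each metric with paired `<metric>_stem` / `<metric>_uas` columns,
#' computes per-plot differences with the fixed sign convention
#' *error = drone estimate − stem map*, then summarizes: mean error (ME),
#' mean percent error (per-plot percents averaged, not ratio of means),
#' mean absolute error (MAE), mean absolute percent error (MAPE), RMSE, and
#' percent RMSE.
#'
#' @param table A data frame shaped like [stand_comparison()]: one row per
#'   plot, paired columns named `<metric>_stem` and `<metric>_uas`.
#' @return A tibble with one row per metric: `metric`, `n`, `me`, `mpe_pct`,
#'   `mae`, `mape_pct`, `rmse`, `rmse_pct`.
#' @export
#' @examples
#' compare_stand_tables(stand_comparison())
compare_stand_tables <- function(table) {
  table <- as_tibble(table)
  stems <- grep("_stem$", names(table), value = TRUE)
  metrics <- sub("_stem$", "", stems)
  metrics <- metrics[paste0(metrics, "_uas") %in% names(table)]
  if (length(metrics) == 0) {
    ss_abort("no paired <metric>_stem / <metric>_uas columns found.",
             "standscan_format_error")
  }
  purrr::map_dfr(metrics, function(m) {
    ref <- table[[paste0(m, "_stem")]]
    est <- table[[paste0(m, "_uas")]]
    if (anyNA(ref) || anyNA(est)) {
      ss_abort(sprintf("metric '%s' has unpaired rows.", m),
               "standscan_validation_error")
    }
    d <- est - ref
    p <- 100 * d / ref
    tibble(metric = m, n = length(d),
           me = mean(d), mpe_pct = mean(p),
           mae = mean(abs(d)), mape_pct = mean(abs(p)),
           rmse = sqrt(mean(d^2)), rmse_pct = sqrt(mean(p^2)))
  })
}
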