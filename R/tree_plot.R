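#' Construct a stem-mapped tree plot
#'
#' A `tree_plot` is a tibble of tree records — one row per tree — carrying the
#' plot identity and its rectangular bounds as attributes. It is the common
#' currency of the package: field stem maps, synthetic stands, and
#' drone-detected tree lists all travel in this shape.
#'
#' Units are fixed throughout the package: coordinates and heights in meters,
#' diameter at breast height (DBH) in centimeters, basal area in m2/ha.
#' Readers never auto-convert.
#'
#' @param trees A data frame with columns `tree_id`, `x_m`, `y_m`, `height_m`
#'   and optionally `dbh_cm`, `crown_radius_m`, `source`, `dbh_origin`.
#'   Missing optional values are `NA`, never 0.
#' @param plot_id Plot label.
#' @param bounds Numeric `c(xmin, ymin, xmax, ymax)` in meters; default a
#'   1-ha square `c(0, 0, 100, 100)`.
#' @param source Default provenance (`"stem_map"` or `"uas"`) applied to rows
#'   lacking a `source` column.
#' @param min_height_m Inventory threshold; trees must be at least this tall
#'   (default 1.37 m, breast height).
#' @param edge_buffer_m Trees may lie up to this far outside `bounds`.
#'
#' @return A tibble of class `tree_plot` with attributes `plot_id` and
#'   `bounds`.
#' @export
#' @examples
#' tree_plot(data.frame(tree_id = "t1", x_m = 5, y_m = 5, height_m = 12))
tree_plot <- function(trees, plot_id = "plot", bounds = c(0, 0, 100, 100),
                      source = "stem_map", min_height_m = 1.37,
                      edge_buffer_m = 0) {
  trees <- as_tibble(trees)
  needed <- c("tree_id", "x_m", "y_m", "height_m")
  missing_cols <- setdiff(needed, names(trees))
  if (length(missing_cols) > 0) {
    ss_abort(paste0("tree table is missing mandatory column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "standscan_format_error")
  }
  if (!"dbh_cm" %in% names(trees)) trees$dbh_cm <- NA_real_
  if (!"crown_radius_m" %in% names(trees)) trees$crown_radius_m <- NA_real_
  if (!"source" %in% names(trees)) trees$source <- source
  if (!"dbh_origin" %in% names(trees)) trees$dbh_origin <- NA_character_
  trees$tree_id <- as.character(trees$tree_id)
  trees <- trees[, c("tree_id", "x_m", "y_m", "height_m", "dbh_cm",
                     "crown_radius_m", "source", "dbh_origin")]
  out <- structure(trees,
                   class = c("tree_plot", class(tibble())),
                   plot_id = plot_id, bounds = as.numeric(bounds))
  validate_tree_plot(out, min_height_m = min_height_m,
                     edge_buffer_m = edge_buffer_m)
  out
}

#' Validate tree-plot invariants
#'
#' Checks unique ids, the inventory height threshold, positive DBH where
#' present, non-negative crown radii, and containment in the plot bounds.
#'
#' @param plot A [tree_plot()].
#' @inheritParams tree_plot
#' @return `plot`, invisibly; aborts on violation.
#' @export
validate_tree_plot <- function(plot, min_height_m = 1.37, edge_buffer_m = 0) {
  if (anyDuplicated(plot$tree_id)) {
    ss_abort("tree ids must be unique within a plot.",
             "standscan_validation_error")
  }
  bad <- !is.finite(plot$x_m) | !is.finite(plot$y_m) | !is.finite(plot$height_m)
  if (any(bad)) {
    ss_abort(paste0("non-numeric coordinate/height in row(s): ",
                    paste(which(bad), collapse = ", ")),
             "standscan_parse_error")
  }
  if (any(plot$height_m < min_height_m)) {
    ss_abort(sprintf("all tree heights must be >= %.2f m.", min_height_m),
             "standscan_validation_error")
  }
  if (any(!is.na(plot$dbh_cm) & plot$dbh_cm <= 0)) {
    ss_abort("dbh_cm must be positive where present.",
             "standscan_validation_error")
  }
  if (any(!is.na(plot$crown_radius_m) & plot$crown_radius_m < 0)) {
    ss_abort("crown_radius_m must be non-negative where present.",
             "standscan_validation_error")
  }
  b <- plot_bounds(plot)
  if (nrow(plot) > 0) {
    inside <- plot$x_m >= b[1] - edge_buffer_m & plot$x_m <= b[3] + edge_buffer_m &
      plot$y_m >= b[2] - edge_buffer_m & plot$y_m <= b[4] + edge_buffer_m
    if (!all(inside)) {
      ss_abort("trees fall outside the plot bounds (+ buffer).",
               "standscan_validation_error")
    }
  }
  invisible(plot)
}

#' @rdname tree_plot
#' @export
plot_bounds <- function(plot) {
  b <- attr(plot, "bounds")
  if (is.null(b)) c(0, 0, 100, 100) else b
}

#' @rdname tree_plot
#' @export
plot_area_ha <- function(plot) {
  b <- plot_bounds(plot)
  (b[3] - b[1]) * (b[4] - b[2]) / 1e4
}

# keep class/attrs after a row-subsetting or mutate-like operation
restamp_tree_plot <- function(trees, template) {
  structure(as_tibble(trees),
            class = c("tree_plot", class(tibble())),
            plot_id = attr(template, "plot_id"),
            bounds = plot_bounds(template))
}

#' Read and write tree-list CSV files
#'
#' Comma-delimited UTF-8 files with a mandatory header and "." decimal mark.
#' Columns: `tree_id, x_m, y_m, height_m, dbh_cm, crown_radius_m, source,
#' dbh_origin`; the last four are optional on read. Unset optional values are
#' written as empty cells, never zeros.
#'
#' @param path File path.
#' @inheritParams tree_plot
#' @return `read_tree_csv()` returns a [tree_plot()]; `write_tree_csv()`
#'   returns `path` invisibly.
#' @export
read_tree_csv <- function(path, source = "stem_map", plot_id = NULL,
                          bounds = c(0, 0, 100, 100), min_height_m = 1.37,
                          edge_buffer_m = 0) {
  if (!file.exists(path)) {
    ss_abort(paste0("file not found: ", path), "standscan_io_error")
  }
  raw <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("tree_id", "x_m", "y_m", "height_m")
  # tolerate the short header spelling id/x/y/height
  alias <- c(id = "tree_id", x = "x_m", y = "y_m", height = "height_m")
  for (a in names(alias)) {
    if (a %in% names(raw) && !alias[[a]] %in% names(raw)) {
      names(raw)[names(raw) == a] <- alias[[a]]
    }
  }
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols) > 0) {
    ss_abort(paste0("CSV is missing mandatory column(s): ",
                    paste(missing_cols, collapse = ", ")),
             "standscan_format_error")
  }
  for (col in c("x_m", "y_m", "height_m", "dbh_cm", "crown_radius_m")) {
    if (col %in% names(raw) && !is.numeric(raw[[col]])) {
      coerced <- suppressWarnings(as.numeric(raw[[col]]))
      bad <- which(!is.na(raw[[col]]) & raw[[col]] != "" & is.na(coerced))
      if (length(bad) > 0) {
        ss_abort(sprintf("non-numeric value in column '%s', row(s): %s",
                         col, paste(bad, collapse = ", ")),
                 "standscan_parse_error")
      }
      raw[[col]] <- coerced
    }
  }
  for (col in c("source", "dbh_origin")) {
    if (col %in% names(raw)) {
      raw[[col]] <- as.character(raw[[col]])
      raw[[col]][raw[[col]] == ""] <- NA_character_
    }
  }
  tree_plot(raw, plot_id = plot_id %||% basename(path), bounds = bounds,
            source = source, min_height_m = min_height_m,
            edge_buffer_m = edge_buffer_m)
}

#' @rdname read_tree_csv
#' @param plot A [tree_plot()].
#' @export
write_tree_csv <- function(plot, path) {
  ok <- tryCatch({
    write.csv(as.data.frame(plot), path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) ss_abort(paste0("cannot write: ", path), "standscan_io_error")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
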