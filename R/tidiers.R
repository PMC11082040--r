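# broom-style tidiers for the package's fitted/derived objects.

#' Tidy a power model
#'
#' @param x A `power_model`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `std.error`.
#' @export
tidy.power_model <- function(x, ...) {
  tibble(term = c("beta1", "beta2"),
         estimate = c(x$beta1, x$beta2),
         std.error = sqrt(pmax(0, diag(x$param_cov))))
}

#' Glance at a power model
#'
#' @param x A `power_model`.
#' @param ... Unused.
#' @return A one-row tibble: `beta1`, `beta2`, `sigma` (residual SE, cm),
#'   `nobs`.
#' @export
glance.power_model <- function(x, ...) {
  tibble(beta1 = x$beta1, beta2 = x$beta2, sigma = x$resid_se_cm, nobs = x$n)
}

#' Tidy a match result
#'
#' @param x A `match_result`.
#' @param ... Unused.
#' @return One row per tree with a `status` of `matched`, `false_positive`,
#'   or `false_negative`; matched rows carry the pairing and errors.
#' @export
tidy.match_result <- function(x, ...) {
  bind_rows(
    mutate(x$matches, status = "matched"),
    tibble(uas_id = x$false_positives, field_id = NA_character_,
           height_error_m = NA_real_, distance_m = NA_real_,
           status = "false_positive"),
    tibble(uas_id = NA_character_, field_id = x$false_negatives,
           height_error_m = NA_real_, distance_m = NA_real_,
           status = "false_negative"))
}

#' Glance at a match result
#'
#' @param x A `match_result`.
#' @param ... Unused.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `f_score`.
#' @export
glance.match_result <- function(x, ...) {
  tp <- nrow(x$matches)
  fp <- length(x$false_positives)
  fn <- length(x$false_negatives)
  tibble(tp = tp, fp = fp, fn = fn,
         precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
         recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
         f_score = f_score(tp, fp, fn))
}

#' Tidy a clump metrics object
#'
#' @param x A `clump_metrics`.
#' @param ... Unused.
#' @return The per-clump tibble.
#' @export
tidy.clump_metrics <- function(x, ...) x$per_clump

#' Glance at a clump metrics object
#'
#' @param x A `clump_metrics`.
#' @param ... Unused.
#' @return A one-row tibble: `n_clumps`, `n_individuals`, `largest_clump`.
#' @export
glance.clump_metrics <- function(x, ...) {
  tibble(n_clumps = nrow(x$per_clump),
         n_individuals = sum(x$per_clump$size == 1),
         largest_clump = max(x$per_clump$size))
}

#' Tidy a crown segmentation
#'
#' @param x A `crown_segmentation`.
#' @param ... Unused.
#' @return The per-treetop crown-area tibble.
#' @export
tidy.crown_segmentation <- function(x, ...) x$crown_area_m2
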