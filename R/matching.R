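# Greedy matching of detected trees to stem-mapped trees, and the detection
# and measurement-error metrics built on the matches.

#' Match detected trees to stem-mapped trees
#'
#' Greedy one-to-one matching. Detected (UAS) trees are processed in
#' descending height order (tall-first stabilizes the outcome; the order is
#' overridable). For each, candidate field trees within `max_dist_m` that are
#' not yet matched are screened for an absolute height error below
#' `max_height_err_m`; the candidate with the smallest height error wins
#' (ties broken by smallest distance, then smallest field id) and is removed
#' from the pool. Unmatched detected trees are false positives; leftover
#' field trees are false negatives. The result is invariant to the row order
#' of either input.
#'
#' @param uas A [tree_plot()] of detected trees.
#' @param field A [tree_plot()] of stem-mapped trees.
#' @param max_dist_m Maximum horizontal match distance (default 4.0 m).
#' @param max_height_err_m Maximum absolute height error (default 2.0 m).
#' @param order Processing order of detected trees: `"height_desc"`
#'   (default), `"height_asc"`, or `"input"` (diagnostic use).
#' @return A list of class `match_result`: `matches` (tibble `uas_id`,
#'   `field_id`, `height_error_m`, `distance_m`), `false_positives`,
#'   `false_negatives` (id vectors).
#' @export
match_trees <- function(uas, field, max_dist_m = 4.0, max_height_err_m = 2.0,
                        order = c("height_desc", "height_asc", "input")) {
  order <- match.arg(order)
  if (max_dist_m <= 0 || max_height_err_m <= 0) {
    ss_abort("match tolerances must be positive.",
             "standscan_parameter_error")
  }
  u_ord <- switch(order,
                  height_desc = order(-uas$height_m, uas$tree_id),
                  height_asc = order(uas$height_m, uas$tree_id),
                  input = seq_len(nrow(uas)))
  avail <- rep(TRUE, nrow(field))
  m_uas <- character(0); m_field <- character(0)
  m_he <- numeric(0); m_d <- numeric(0)
  for (i in u_ord) {
    d <- sqrt((field$x_m - uas$x_m[i])^2 + (field$y_m - uas$y_m[i])^2)
    he <- abs(field$height_m - uas$height_m[i])
    cand <- which(avail & d <= max_dist_m & he < max_height_err_m)
    if (length(cand) == 0) next
    pick <- cand[order(he[cand], d[cand], field$tree_id[cand])][1]
    avail[pick] <- FALSE
    m_uas <- c(m_uas, uas$tree_id[i])
    m_field <- c(m_field, field$tree_id[pick])
    m_he <- c(m_he, uas$height_m[i] - field$height_m[pick])
    m_d <- c(m_d, d[pick])
  }
  structure(list(
    matches = tibble(uas_id = m_uas, field_id = m_field,
                     height_error_m = m_he, distance_m = m_d),
    false_positives = setdiff(uas$tree_id, m_uas),
    false_negatives = field$tree_id[avail]),
    class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> TP %d, FP %d, FN %d (F = %.3f)\n",
              nrow(x$matches), length(x$false_positives),
              length(x$false_negatives),
              f_score(nrow(x$matches), length(x$false_positives),
                      length(x$false_negatives))))
  invisible(x)
}

#' F-score of tree extraction
#'
#' Harmonic mean of precision `tp / (tp + fp)` and recall `tp / (tp + fn)`;
#' 0 when there are no true positives.
#'
#' @param tp,fp,fn Non-negative counts, not all zero.
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' f_score(8, 2, 2)  # 0.8
f_score <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0) || (tp + fp + fn) == 0) {
    ss_abort("counts must be >= 0 and not all zero.",
             "standscan_domain_error")
  }
  if (tp == 0) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * (p * r) / (p + r)
}

#' Detection rates by dominance class
#'
#' Summarizes a [match_trees()] result per dominance class (understory
#' < 5 m, intermediate 5-15 m, overstory > 15 m) and overall. True positives
#' and false negatives are classed by the *field* height; false positives by
#' the *detected* height. Rates: `tp_rate = TP/(TP+FN)`,
#' `fn_rate = FN/(TP+FN)`, `fp_rate = FP/(TP+FP)`, plus the F-score. Classes
#' with no trees on either side are dropped (absent, not zero).
#'
#' @param match A `match_result` from [match_trees()].
#' @param uas,field The tree plots the match was produced from.
#' @return A tibble of class `detection_rates`: `class`, `tp`, `fp`, `fn`,
#'   `tp_rate`, `fp_rate`, `fn_rate`, `f_score`.
#' @export
detection_rates <- function(match, uas, field) {
  f_cls <- setNames(dominance_class(field$height_m), field$tree_id)
  u_cls <- setNames(dominance_class(uas$height_m), uas$tree_id)
  classes <- c("understory", "intermediate", "overstory")
  rows <- purrr::map_dfr(c(classes, "all"), function(cl) {
    in_cl <- function(x) if (cl == "all") rep(TRUE, length(x)) else x == cl
    tp <- sum(in_cl(f_cls[match$matches$field_id]))
    fn <- sum(in_cl(f_cls[match$false_negatives]))
    fp <- sum(in_cl(u_cls[match$false_positives]))
    if (tp + fn + fp == 0) return(tibble())
    tibble(class = cl, tp = tp, fp = fp, fn = fn,
           tp_rate = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
           fp_rate = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
           fn_rate = if (tp + fn > 0) fn / (tp + fn) else NA_real_,
           f_score = f_score(tp, fp, fn))
  })
  structure(rows, class = c("detection_rates", class(tibble())))
}

#' Height and DBH error summary by tree size class
#'
#' For matched pairs, errors are *detected minus field*. Mean error (ME) and
#' RMSE of height — and of DBH where both sides carry one — are reported per
#' 5-m field-height class (`[0,5)`, `[5,10)`, `[10,15)`, `[15,20)`,
#' `[20,Inf)`) and overall.
#'
#' @inheritParams detection_rates
#' @return A tibble: `class`, `n`, `me_height_m`, `rmse_height_m`, `n_dbh`,
#'   `me_dbh_cm`, `rmse_dbh_cm`.
#' @export
error_summary <- function(match, uas, field) {
  if (nrow(match$matches) == 0) {
    return(tibble(class = character(0), n = integer(0),
                  me_height_m = numeric(0), rmse_height_m = numeric(0),
                  n_dbh = integer(0), me_dbh_cm = numeric(0),
                  rmse_dbh_cm = numeric(0)))
  }
  fh <- setNames(field$height_m, field$tree_id)
  fd <- setNames(field$dbh_cm, field$tree_id)
  ud <- setNames(uas$dbh_cm, uas$tree_id)
  m <- match$matches
  m$field_height <- fh[m$field_id]
  m$dbh_error <- ud[m$uas_id] - fd[m$field_id]
  breaks <- c(0, 5, 10, 15, 20, Inf)
  lab <- c("[0,5)", "[5,10)", "[10,15)", "[15,20)", "[20,Inf)")
  m$class <- as.character(cut(m$field_height, breaks, labels = lab,
                              right = FALSE))
  one <- function(sub, cl) {
    d_ok <- !is.na(sub$dbh_error)
    tibble(class = cl, n = nrow(sub),
           me_height_m = mean(sub$height_error_m),
           rmse_height_m = sqrt(mean(sub$height_error_m^2)),
           n_dbh = sum(d_ok),
           me_dbh_cm = if (any(d_ok)) mean(sub$dbh_error[d_ok]) else NA_real_,
           rmse_dbh_cm = if (any(d_ok)) sqrt(mean(sub$dbh_error[d_ok]^2))
           else NA_real_)
  }
  per <- purrr::map_dfr(lab[lab %in% m$class],
                        function(cl) one(m[m$class == cl, ], cl))
  bind_rows(per, one(m, "all"))
}
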