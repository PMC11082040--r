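# One-way ANOVA machinery for stem-map vs detected comparisons of structure
# metrics, with Bonferroni adjustment across class-level comparisons.

#' One-way analysis of variance
#'
#' Classical between/within sum-of-squares F test (fixed effects, one
#' factor), computed through [stats::lm()]/[stats::anova()]. Zero
#' within-group variance with unequal group means is reported as the p = 0
#' boundary with a flag rather than an error.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, each non-empty, total n >
#'   number of groups).
#' @return A one-row tibble of class `anova_result`: `f_stat`, `p_value`,
#'   `df_between`, `df_within`, `n`, `degenerate`.
#' @export
one_way_anova <- function(values, groups) {
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]
  groups <- factor(groups[ok])
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2 || n <= k) {
    ss_abort("need >= 2 non-empty groups and n > #groups.",
             "standscan_parameter_error")
  }
  ss_within <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  if (ss_within == 0) {
    means <- tapply(values, groups, mean)
    if (max(means) - min(means) > 0) {
      return(structure(tibble(f_stat = Inf, p_value = 0,
                              df_between = k - 1L, df_within = n - k,
                              n = n, degenerate = TRUE),
                       class = c("anova_result", class(tibble()))))
    }
  }
  fit <- anova(lm(values ~ groups))
  structure(tibble(f_stat = fit$`F value`[1], p_value = fit$`Pr(>F)`[1],
                   df_between = fit$Df[1], df_within = fit$Df[2],
                   n = n, degenerate = FALSE),
            class = c("anova_result", class(tibble())))
}

#' Bonferroni adjustment
#'
#' `min(1, k * p)`: the raw p-value scaled by the number of comparisons in
#' its family and capped at 1.
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param k Number of comparisons (>= 1).
#' @return Adjusted p-value(s).
#' @export
#' @examples
#' bonferroni_adjust(0.01, 5)  # 0.05
bonferroni_adjust <- function(p, k) {
  if (any(k < 1)) {
    ss_abort("k must be >= 1.", "standscan_domain_error")
  }
  if (any(p < 0 | p > 1)) {
    ss_abort("p must be in [0, 1].", "standscan_domain_error")
  }
  pmin(1, k * p)
}

#' Compare structure metrics between two tree-list sources
#'
#' Runs one one-way ANOVA per metric x class, comparing the stem-map and
#' detected values, and Bonferroni-adjusts each raw p-value by the number of
#' class-level comparisons within its metric family (by default 5 for clump
#' counts, basal-area percent, crown area, and openings; 4 for height CV,
#' which has no `individual` class).
#'
#' @param stem_long,uas_long Long-format tibbles with columns `metric`,
#'   `class`, `value` (one row per observation: per plot or per clump
#'   depending on the metric).
#' @param k_map Named integer vector mapping metric name to its family's
#'   comparison count; metrics absent from `k_map` use the number of classes
#'   observed for that metric.
#' @return A tibble: `metric`, `class`, `n`, `mean_stem`, `sd_stem`,
#'   `mean_uas`, `sd_uas`, `f_stat`, `p_value`, `p_adjusted`,
#'   `comparable`.
#' @export
compare_structure_metrics <- function(stem_long, uas_long,
                                      k_map = c(n_clumps = 5, ba_pct = 5,
                                                crown_area_m2 = 5,
                                                opening_pct = 5,
                                                height_cv_pct = 4)) {
  stem_long <- mutate(as_tibble(stem_long), source = "stem_map")
  uas_long <- mutate(as_tibble(uas_long), source = "uas")
  all <- bind_rows(stem_long, uas_long)
  combos <- unique(all[, c("metric", "class")])
  purrr::map_dfr(seq_len(nrow(combos)), function(i) {
    m <- combos$metric[i]; cl <- combos$class[i]
    sub <- all[all$metric == m & all$class == cl & is.finite(all$value), ]
    srcs <- unique(sub$source)
    k <- if (m %in% names(k_map)) k_map[[m]] else {
      length(unique(all$class[all$metric == m]))
    }
    base <- tibble(metric = m, class = as.character(cl), n = nrow(sub),
                   mean_stem = mean(sub$value[sub$source == "stem_map"]),
                   sd_stem = sd(sub$value[sub$source == "stem_map"]),
                   mean_uas = mean(sub$value[sub$source == "uas"]),
                   sd_uas = sd(sub$value[sub$source == "uas"]))
    if (length(srcs) < 2 || nrow(sub) <= 2 ||
        min(table(sub$source)) < 1) {
      # class present in one source only: reported, not silently dropped
      return(mutate(base, f_stat = NA_real_, p_value = NA_real_,
                    p_adjusted = NA_real_, comparable = FALSE))
    }
    a <- one_way_anova(sub$value, sub$source)
    mutate(base, f_stat = a$f_stat, p_value = a$p_value,
           p_adjusted = bonferroni_adjust(a$p_value, k), comparable = TRUE)
  })
}
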