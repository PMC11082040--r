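# Synthetic stem-mapped stands emulating four thinning-treatment archetypes,
# plus renderers (CHM, breast-height slice) and a detection-error
# perturbation model, so the whole pipeline can be exercised without field
# data.

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Treatment archetypes for synthetic stands
#'
#' Describes the spatial process and height structure of a stand under one of
#' four silvicultural archetypes: `SGR` (small-group retention: few dense
#' groups of large trees plus heavy sapling patches), `CT` (commercial
#' thinning from below: evenly spaced overstory, minimum ~4.9 m spacing,
#' little understory), `FS_On` and `FS_Off` (free selection with and without
#' overstory-aware pre-commercial spacing; `FS_On` keeps more understory).
#' Overstory placement uses a parent-offspring (Thomas-type) cluster process
#' when `clump_parent_intensity > 0`, otherwise a hard-core inhibition
#' process at `min_spacing_m`. Understory trees are placed inside randomly
#' located circular regeneration patches.
#'
#' @param name One of `"SGR"`, `"CT"`, `"FS_On"`, `"FS_Off"`, `"custom"`.
#' @param ... Field overrides (see Details in the package vignette):
#'   `overstory_density`, `clump_parent_intensity`, `offspring_mean`,
#'   `offspring_sd_m`, `understory_patch_density`,
#'   `understory_patch_fraction`, `patch_radius_m`, `min_spacing_m`,
#'   `height_law` (list with `overstory`/`understory` lognormal
#'   `meanlog`/`sdlog`).
#' @return A list of class `treatment_archetype`.
#' @export
treatment_archetype <- function(name = c("SGR", "CT", "FS_On", "FS_Off",
                                         "custom"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    SGR = list(overstory_density = 60, clump_parent_intensity = 3,
               offspring_mean = 20, offspring_sd_m = 4,
               understory_patch_density = 1000,
               understory_patch_fraction = 0.25,
               min_spacing_m = 0,
               height_law = list(
                 overstory = c(meanlog = log(18), sdlog = 0.25),
                 understory = c(meanlog = log(2.5), sdlog = 0.35))),
    CT = list(overstory_density = 180, clump_parent_intensity = 0,
              offspring_mean = 0, offspring_sd_m = 0,
              understory_patch_density = 0,
              understory_patch_fraction = 0,
              min_spacing_m = 4.9,
              height_law = list(
                overstory = c(meanlog = log(14), sdlog = 0.25),
                understory = c(meanlog = log(2.5), sdlog = 0.35))),
    FS_On = list(overstory_density = 120, clump_parent_intensity = 12,
                 offspring_mean = 10, offspring_sd_m = 6,
                 understory_patch_density = 800,
                 understory_patch_fraction = 0.2,
                 min_spacing_m = 0,
                 height_law = list(
                   overstory = c(meanlog = log(15), sdlog = 0.3),
                   understory = c(meanlog = log(2.8), sdlog = 0.4))),
    FS_Off = list(overstory_density = 208, clump_parent_intensity = 26,
                  offspring_mean = 8, offspring_sd_m = 6,
                  understory_patch_density = 600,
                  understory_patch_fraction = 0.08,
                  min_spacing_m = 0,
                  height_law = list(
                    overstory = c(meanlog = log(15), sdlog = 0.3),
                    understory = c(meanlog = log(2.8), sdlog = 0.4))),
    custom = list(overstory_density = 100, clump_parent_intensity = 0,
                  offspring_mean = 0, offspring_sd_m = 0,
                  understory_patch_density = 0,
                  understory_patch_fraction = 0,
                  min_spacing_m = 0,
                  height_law = list(
                    overstory = c(meanlog = log(15), sdlog = 0.3),
                    understory = c(meanlog = log(2.5), sdlog = 0.35))))
  base$patch_radius_m <- 10
  out <- utils::modifyList(base, list(...))
  out$name <- name
  dens <- c(out$overstory_density, out$clump_parent_intensity,
            out$understory_patch_density)
  if (any(dens < 0) || out$understory_patch_fraction < 0 ||
      out$understory_patch_fraction > 1 || out$min_spacing_m < 0) {
    ss_abort("archetype densities must be >= 0, patch fraction in [0, 1].",
             "standscan_parameter_error")
  }
  structure(out, class = "treatment_archetype")
}

#' Generate a stem-mapped synthetic stand
#'
#' Places overstory trees by the archetype's spatial process (Thomas-type
#' cluster process with parents drawn in a buffered region, or hard-core
#' dart throwing with rejection capped at 10^4 attempts per tree) and
#' understory trees inside circular regeneration patches, then draws heights
#' per stratum from the archetype's lognormal laws (truncated at the 1.37 m
#' inventory threshold; understory capped below 5 m).
#'
#' @param archetype A [treatment_archetype()].
#' @param bounds Plot rectangle `c(xmin, ymin, xmax, ymax)` (m).
#' @param seed Integer seed; the same seed always reproduces the same stand.
#' @param plot_id Label for the generated plot.
#' @return A [tree_plot()] with `source = "stem_map"`.
#' @export
generate_stem_map <- function(archetype, bounds = c(0, 0, 100, 100),
                              seed = 1, plot_id = archetype$name) {
  stopifnot(inherits(archetype, "treatment_archetype"))
  area_ha <- (bounds[3] - bounds[1]) * (bounds[4] - bounds[2]) / 1e4
  tot <- archetype$overstory_density +
    archetype$understory_patch_density * archetype$understory_patch_fraction
  if (tot > 1e5) {
    ss_abort("archetype implies more than 1e5 trees per hectare.",
             "standscan_parameter_error")
  }
  with_seed(seed, {
    over <- place_overstory(archetype, bounds)
    under <- place_understory(archetype, bounds)
    hl <- archetype$height_law
    h_over <- rlnorm_trunc(nrow(over), hl$overstory["meanlog"],
                           hl$overstory["sdlog"], lo = 1.37)
    h_under <- rlnorm_trunc(nrow(under), hl$understory["meanlog"],
                            hl$understory["sdlog"], lo = 1.37, hi = 4.99)
    trees <- tibble(
      x_m = c(over$x, under$x), y_m = c(over$y, under$y),
      height_m = c(h_over, h_under),
      stratum = rep(c("overstory", "understory"),
                    c(nrow(over), nrow(under))))
    trees$tree_id <- sprintf("t%04d", seq_len(nrow(trees)))
    p <- tree_plot(trees[, c("tree_id", "x_m", "y_m", "height_m")],
                   plot_id = plot_id, bounds = bounds, source = "stem_map")
    p
  })
}

rlnorm_trunc <- function(n, meanlog, sdlog, lo = -Inf, hi = Inf) {
  if (n == 0) return(numeric(0))
  x <- stats::rlnorm(n, meanlog, sdlog)
  bad <- which(x < lo | x > hi)
  tries <- 0
  while (length(bad) > 0 && tries < 1000) {
    x[bad] <- stats::rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[x[bad] < lo | x[bad] > hi]
    tries <- tries + 1
  }
  pmin(pmax(x, lo), hi)
}

place_overstory <- function(a, bounds) {
  area_ha <- (bounds[3] - bounds[1]) * (bounds[4] - bounds[2]) / 1e4
  if (a$overstory_density <= 0) {
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  if (a$clump_parent_intensity > 0) {
    # Thomas-type: parents in a buffered region so edge clusters still spill in
    buf <- 3 * a$offspring_sd_m
    bx <- c(bounds[1] - buf, bounds[3] + buf)
    by <- c(bounds[2] - buf, bounds[4] + buf)
    area_buf_ha <- diff(bx) * diff(by) / 1e4
    n_par <- rpois(1, a$clump_parent_intensity * area_buf_ha)
    if (n_par == 0) return(data.frame(x = numeric(0), y = numeric(0)))
    px <- runif(n_par, bx[1], bx[2]); py <- runif(n_par, by[1], by[2])
    n_off <- rpois(n_par, a$offspring_mean)
    x <- rep(px, n_off) + rnorm(sum(n_off), 0, a$offspring_sd_m)
    y <- rep(py, n_off) + rnorm(sum(n_off), 0, a$offspring_sd_m)
    keep <- x >= bounds[1] & x <= bounds[3] & y >= bounds[2] & y <= bounds[4]
    data.frame(x = x[keep], y = y[keep])
  } else {
    n <- rpois(1, a$overstory_density * area_ha)
    if (a$min_spacing_m <= 0) {
      return(data.frame(x = runif(n, bounds[1], bounds[3]),
                        y = runif(n, bounds[2], bounds[4])))
    }
    # hard-core inhibition by dart throwing
    x <- numeric(0); y <- numeric(0)
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(1e4)) {
        cx <- runif(1, bounds[1], bounds[3])
        cy <- runif(1, bounds[2], bounds[4])
        if (length(x) == 0 ||
            min((x - cx)^2 + (y - cy)^2) >= a$min_spacing_m^2) {
          x <- c(x, cx); y <- c(y, cy); placed <- TRUE
          break
        }
      }
      if (!placed) break  # plot saturated at this spacing
    }
    data.frame(x = x, y = y)
  }
}

place_understory <- function(a, bounds) {
  if (a$understory_patch_density <= 0 || a$understory_patch_fraction <= 0) {
    return(data.frame(x = numeric(0), y = numeric(0)))
  }
  area <- (bounds[3] - bounds[1]) * (bounds[4] - bounds[2])
  r <- a$patch_radius_m
  n_patch <- max(1L, round(a$understory_patch_fraction * area / (pi * r^2)))
  cx <- runif(n_patch, bounds[1], bounds[3])
  cy <- runif(n_patch, bounds[2], bounds[4])
  n_in <- rpois(n_patch, a$understory_patch_density * pi * r^2 / 1e4)
  if (sum(n_in) == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  # uniform in each patch disk
  th <- runif(sum(n_in), 0, 2 * pi)
  rr <- r * sqrt(runif(sum(n_in)))
  x <- rep(cx, n_in) + rr * cos(th)
  y <- rep(cy, n_in) + rr * sin(th)
  keep <- x >= bounds[1] & x <= bounds[3] & y >= bounds[2] & y <= bounds[4]
  data.frame(x = x[keep], y = y[keep])
}

#' Height-diameter and crown allometry parameters
#'
#' DBH follows the power law `dbh_cm = beta1 * height_m^beta2` with additive
#' Gaussian noise; crown radius is linear in height. Defaults reproduce the
#' mean site-level power model for ponderosa pine reported for this kind of
#' stand (`beta1 = 4.29`, `beta2 = 0.68`, residual SD 1.20 cm) and give a
#' ~3 m crown radius at 18 m height.
#'
#' @param beta1,beta2 Power-law coefficient and exponent (both > 0).
#' @param resid_sd_cm Gaussian DBH noise SD (cm).
#' @param crown_slope Crown radius gained per meter of height.
#' @param crown_intercept_m Crown radius at zero height (m).
#' @return A list of class `allometry_params`.
#' @export
allometry_params <- function(beta1 = 4.29, beta2 = 0.68, resid_sd_cm = 1.20,
                             crown_slope = 0.14, crown_intercept_m = 0.5) {
  if (beta1 <= 0 || beta2 <= 0 || resid_sd_cm < 0) {
    ss_abort("beta1, beta2 must be > 0 and resid_sd_cm >= 0.",
             "standscan_parameter_error")
  }
  structure(list(beta1 = beta1, beta2 = beta2, resid_sd_cm = resid_sd_cm,
                 crown_slope = crown_slope,
                 crown_intercept_m = crown_intercept_m),
            class = "allometry_params")
}

#' Assign DBH and crown radius to a stand by allometry
#'
#' `dbh_cm = beta1 * height^beta2 + N(0, resid_sd_cm)`, redrawn until
#' positive; `crown_radius_m = crown_intercept + crown_slope * height`,
#' floored at 0.3 m. Sets `dbh_origin = "measured"`.
#'
#' @param plot A [tree_plot()] with heights.
#' @param params An [allometry_params()].
#' @param seed Integer seed for the noise draw.
#' @return The plot with `dbh_cm`, `crown_radius_m`, `dbh_origin` filled.
#' @export
assign_allometry <- function(plot, params = allometry_params(), seed = 1) {
  stopifnot(inherits(params, "allometry_params"))
  if (nrow(plot) == 0) return(plot)
  if (any(plot$height_m <= 0)) {
    ss_abort("heights must be positive.", "standscan_validation_error")
  }
  with_seed(seed, {
    mu <- params$beta1 * plot$height_m^params$beta2
    dbh <- mu + rnorm(nrow(plot), 0, params$resid_sd_cm)
    bad <- which(dbh <= 0)
    while (length(bad) > 0) {
      dbh[bad] <- mu[bad] + rnorm(length(bad), 0, params$resid_sd_cm)
      bad <- bad[dbh[bad] <= 0]
    }
    out <- plot
    out$dbh_cm <- dbh
    out$crown_radius_m <- pmax(0.3, params$crown_intercept_m +
                                 params$crown_slope * plot$height_m)
    out$dbh_origin <- "measured"
    restamp_tree_plot(out, plot)
  })
}

#' Render a canopy height model from a tree list
#'
#' Each tree contributes a generalized-paraboloid crown surface
#' `h(r) = height * (1 - (r / crown_radius)^crown_exponent)` for
#' `r <= crown_radius`; a cell's value is the maximum over all trees (0 where
#' no crown reaches). The cell containing each stem records the full tree
#' height, so the apex of an isolated tree equals its height exactly.
#'
#' @param plot A [tree_plot()] with heights and crown radii.
#' @param cell_size_m Grid resolution (m), default 0.10.
#' @param crown_exponent Crown shape exponent (2 = paraboloid).
#' @return A [chm()] covering the plot bounds.
#' @export
render_chm <- function(plot, cell_size_m = 0.1, crown_exponent = 2) {
  check_positive_scalar(cell_size_m, "cell_size_m")
  check_positive_scalar(crown_exponent, "crown_exponent")
  b <- plot_bounds(plot)
  nx <- max(1L, round((b[3] - b[1]) / cell_size_m))
  ny <- max(1L, round((b[4] - b[2]) / cell_size_m))
  vals <- matrix(0, nrow = ny, ncol = nx)
  if (nrow(plot) > 0 && anyNA(plot$crown_radius_m)) {
    ss_abort("all trees need a crown radius to render a CHM.",
             "standscan_accounting_error")
  }
  cx <- b[1] + (seq_len(nx) - 0.5) * cell_size_m
  cy <- b[2] + (seq_len(ny) - 0.5) * cell_size_m
  for (i in seq_len(nrow(plot))) {
    x0 <- plot$x_m[i]; y0 <- plot$y_m[i]
    R <- plot$crown_radius_m[i]; h <- plot$height_m[i]
    jx <- which(abs(cx - x0) <= R)
    jy <- which(abs(cy - y0) <= R)
    if (length(jx) && length(jy)) {
      r <- sqrt(outer((cy[jy] - y0)^2, (cx[jx] - x0)^2, `+`))
      surf <- h * (1 - (r / R)^crown_exponent)
      surf[r > R] <- 0
      vals[jy, jx] <- pmax(vals[jy, jx], surf)
    }
    # stem cell carries the apex height
    sx <- min(nx, max(1L, ceiling((x0 - b[1]) / cell_size_m)))
    sy <- min(ny, max(1L, ceiling((y0 - b[2]) / cell_size_m)))
    vals[sy, sx] <- max(vals[sy, sx], h)
  }
  chm(vals, origin = b[1:2], cell_size_m = cell_size_m)
}

#' Simulate a breast-height point-cloud slice
#'
#' Emulates the 1.32-1.42 m slice of a height-normalized photogrammetric
#' cloud: each tree taller than 1.42 m contributes `pts_per_stem` points on
#' its stem circle (radius `dbh_cm / 200` m) with Gaussian radial noise, plus
#' optional branch-like clutter scattered uniformly inside crowns at slice
#' height.
#'
#' @param plot A [tree_plot()] with DBH (and crown radii if `clutter_fraction
#'   > 0`).
#' @param pts_per_stem Points per stem circle (>= 3).
#' @param radial_sd_m Radial Gaussian noise SD (m).
#' @param clutter_fraction Clutter points as a fraction of stem points.
#' @param seed Integer seed.
#' @return A [point_cloud()] with z in `[1.32, 1.42]`.
#' @export
simulate_breast_height_slice <- function(plot, pts_per_stem = 48,
                                         radial_sd_m = 0,
                                         clutter_fraction = 0, seed = 1) {
  if (pts_per_stem < 3) {
    ss_abort("pts_per_stem must be >= 3 (circle fit underdetermined).",
             "standscan_parameter_error")
  }
  tall <- plot[plot$height_m > 1.42, , drop = FALSE]
  if (nrow(tall) > 0 && anyNA(tall$dbh_cm)) {
    ss_abort("all sliced trees need DBH.", "standscan_accounting_error")
  }
  with_seed(seed, {
    n_stem <- nrow(tall) * pts_per_stem
    if (n_stem > 0) {
      th <- runif(n_stem, 0, 2 * pi)
      r0 <- rep(tall$dbh_cm / 200, each = pts_per_stem)
      r <- pmax(0, r0 + rnorm(n_stem, 0, radial_sd_m))
      x <- rep(tall$x_m, each = pts_per_stem) + r * cos(th)
      y <- rep(tall$y_m, each = pts_per_stem) + r * sin(th)
      z <- runif(n_stem, 1.32, 1.42)
    } else {
      x <- y <- z <- numeric(0)
    }
    n_clut <- round(clutter_fraction * n_stem)
    if (n_clut > 0) {
      pick <- sample.int(nrow(tall), n_clut, replace = TRUE)
      cr <- tall$crown_radius_m[pick]
      if (anyNA(cr)) {
        ss_abort("clutter simulation needs crown radii.",
                 "standscan_accounting_error")
      }
      th <- runif(n_clut, 0, 2 * pi)
      rr <- cr * sqrt(runif(n_clut))
      x <- c(x, tall$x_m[pick] + rr * cos(th))
      y <- c(y, tall$y_m[pick] + rr * sin(th))
      z <- c(z, runif(n_clut, 1.32, 1.42))
    }
    point_cloud(tibble(x_m = x, y_m = y, z_m = z))
  })
}

#' Detection-error perturbation parameters
#'
#' Rates are indexed by dominance class (`understory` < 5 m, `intermediate`
#' 5-15 m, `overstory` > 15 m). `fn_rate_by_class` is the probability that a
#' truth tree is missed; `fp_rate_by_class` is the *target false-positive
#' rate* FP/(TP+FP) per class — spurious trees are added with expected count
#' `n_surviving * p / (1 - p)` so the measured rate matches the parameter.
#' Defaults emulate the error structure reported for drone inventories of
#' treated ponderosa pine stands: understory false positives dominate
#' (~61%), detection improves monotonically with height, heights carry a
#' +0.36 m bias and ~1.3 m RMSE.
#'
#' @param fn_rate_by_class,fp_rate_by_class Named numeric
#'   (`understory`, `intermediate`, `overstory`) in `[0, 1]`.
#' @param xy_sd_m Positional jitter SD (m).
#' @param height_bias_m Additive height bias (m).
#' @param height_sd_m Height noise SD (m).
#' @param ingrowth_rate Density (trees/ha) of new small trees (1.37-2.0 m)
#'   emulating ingrowth between field and flight campaigns.
#' @return A list of class `perturbation_params`.
#' @export
perturbation_params <- function(
    fn_rate_by_class = c(understory = 0.30, intermediate = 0.12,
                         overstory = 0.05),
    fp_rate_by_class = c(understory = 0.614, intermediate = 0.20,
                         overstory = 0.10),
    xy_sd_m = 0.5, height_bias_m = 0.36, height_sd_m = 1.27,
    ingrowth_rate = 0) {
  rates <- c(fn_rate_by_class, fp_rate_by_class)
  if (any(rates < 0) || any(rates > 1) || xy_sd_m < 0 || height_sd_m < 0 ||
      ingrowth_rate < 0) {
    ss_abort("rates must be in [0, 1] and SDs >= 0.",
             "standscan_parameter_error")
  }
  structure(list(fn_rate_by_class = fn_rate_by_class,
                 fp_rate_by_class = fp_rate_by_class,
                 xy_sd_m = xy_sd_m, height_bias_m = height_bias_m,
                 height_sd_m = height_sd_m, ingrowth_rate = ingrowth_rate),
            class = "perturbation_params")
}

#' Perturb a truth stand into a synthetic detected tree list
#'
#' Deletes truth trees per dominance class with the class's false-negative
#' rate, jitters surviving positions and heights, and adds spurious and
#' ingrowth trees, producing a tree list that behaves like the output of an
#' imperfect detector. Surviving trees keep their truth `tree_id`; the
#' mapping is therefore available to test oracles, while spurious trees get
#' ids prefixed `fp` and ingrowth `in`.
#'
#' @param plot A truth [tree_plot()].
#' @param params A [perturbation_params()].
#' @param seed Integer seed.
#' @return A [tree_plot()] with `source = "uas"`.
#' @export
perturb_to_uas <- function(plot, params = perturbation_params(), seed = 1) {
  stopifnot(inherits(params, "perturbation_params"))
  b <- plot_bounds(plot)
  with_seed(seed, {
    cls <- dominance_class(plot$height_m)
    fn <- params$fn_rate_by_class[cls]
    keep <- runif(nrow(plot)) >= ifelse(is.na(fn), 0, fn)
    surv <- plot[keep, , drop = FALSE]
    if (nrow(surv) > 0) {
      surv$x_m <- pmin(pmax(surv$x_m + rnorm(nrow(surv), 0, params$xy_sd_m),
                            b[1]), b[3])
      surv$y_m <- pmin(pmax(surv$y_m + rnorm(nrow(surv), 0, params$xy_sd_m),
                            b[2]), b[4])
      surv$height_m <- pmax(1.37, surv$height_m + params$height_bias_m +
                              rnorm(nrow(surv), 0, params$height_sd_m))
    }
    # spurious trees per class, count tuned to the target FP/(TP+FP) rate
    surv_cls <- dominance_class(surv$height_m)
    sp <- purrr::map_dfr(names(params$fp_rate_by_class), function(cl) {
      p <- params$fp_rate_by_class[[cl]]
      if (p <= 0) return(tibble())
      n_surv <- sum(surv_cls == cl)
      lam <- n_surv * p / (1 - p)
      n_sp <- rpois(1, lam)
      if (n_sp == 0) return(tibble())
      hr <- switch(cl, understory = c(1.37, 4.99),
                   intermediate = c(5, 15),
                   overstory = c(15.01, max(20, max(plot$height_m, 15) * 1.1)))
      tibble(x_m = runif(n_sp, b[1], b[3]), y_m = runif(n_sp, b[2], b[4]),
             height_m = runif(n_sp, hr[1], hr[2]))
    })
    n_in <- rpois(1, params$ingrowth_rate * plot_area_ha(plot))
    ing <- tibble(x_m = runif(n_in, b[1], b[3]),
                  y_m = runif(n_in, b[2], b[4]),
                  height_m = runif(n_in, 1.37, 2.0))
    extra <- bind_rows(sp, ing)
    if (nrow(extra) > 0) {
      extra$tree_id <- c(sprintf("fp%04d", seq_len(nrow(sp))),
                         sprintf("in%04d", seq_len(n_in)))
      extra$dbh_cm <- NA_real_
      extra$crown_radius_m <- NA_real_
      extra$dbh_origin <- NA_character_
    }
    out <- bind_rows(as_tibble(surv), extra)
    out$source <- "uas"
    tree_plot(out, plot_id = paste0(attr(plot, "plot_id"), "-uas"),
              bounds = b, source = "uas")
  })
}

#' Dominance class of a tree height
#'
#' `understory` below 5 m, `intermediate` 5-15 m inclusive, `overstory`
#' above 15 m.
#'
#' @param height_m Numeric vector of heights (m).
#' @return Character vector of class labels.
#' @export
dominance_class <- function(height_m) {
  ifelse(height_m < 5, "understory",
         ifelse(height_m <= 15, "intermediate", "overstory"))
}
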