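# Breast-height circle fitting, height-diameter power models, prediction
# bounds, and DBH imputation.

#' Least-squares circle fit
#'
#' Fits a circle to 2-D points: algebraic (Kasa) least squares for the
#' initial estimate, refined by Gauss-Newton minimization of geometric
#' (radial) distance. Reports the RMS radial residual of the refined fit.
#'
#' @param points Matrix or data frame of x, y coordinates (m), >= 3
#'   non-collinear points.
#' @param max_iter,tol Gauss-Newton controls.
#' @return A one-row tibble of class `circle_fit`: `center_x_m`,
#'   `center_y_m`, `radius_m`, `rms_m`, `n_pts`.
#' @export
#' @examples
#' th <- seq(0, 2 * pi, length.out = 9)[-9]
#' fit_circle_ls(cbind(2 + 0.15 * cos(th), 3 + 0.15 * sin(th)))
fit_circle_ls <- function(points, max_iter = 100, tol = 1e-12) {
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  storage.mode(pts) <- "double"
  n <- nrow(pts)
  if (n < 3) {
    ss_abort("circle fit needs at least 3 points.",
             "standscan_degenerate_fit_error")
  }
  x <- pts[, 1]; y <- pts[, 2]
  # Kasa: x^2 + y^2 = 2a x + 2b y + c
  A <- cbind(2 * x, 2 * y, 1)
  rhs <- x^2 + y^2
  sol <- tryCatch(qr.solve(A, rhs), error = function(e) NULL)
  if (is.null(sol) || !all(is.finite(sol)) ||
      sol[3] + sol[1]^2 + sol[2]^2 <= 0) {
    ss_abort("points are collinear or otherwise degenerate for a circle fit.",
             "standscan_degenerate_fit_error")
  }
  cx <- sol[1]; cy <- sol[2]
  r <- sqrt(sol[3] + cx^2 + cy^2)
  # Gauss-Newton on geometric distance
  for (it in seq_len(max_iter)) {
    dx <- x - cx; dy <- y - cy
    di <- sqrt(dx^2 + dy^2)
    if (any(di == 0)) break
    res <- di - r
    J <- cbind(-dx / di, -dy / di, -1)
    step <- tryCatch(qr.solve(J, -res), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) break
    cx <- cx + step[1]; cy <- cy + step[2]; r <- r + step[3]
    if (sqrt(sum(step^2)) < tol * max(1, r)) break
  }
  di <- sqrt((x - cx)^2 + (y - cy)^2)
  structure(tibble(center_x_m = cx, center_y_m = cy, radius_m = r,
                   rms_m = sqrt(mean((di - r)^2)), n_pts = n),
            class = c("circle_fit", class(tibble())))
}

#' Extract DBH for one tree from a breast-height slice
#'
#' Collects slice points (z in `[1.32, 1.42]` m) within `search_radius_m` of
#' the detected stem location, projects them to the plane, and circle-fits
#' them. The fit is discarded (returns `NULL`) when fewer than `min_points`
#' points are available, when the relative radial scatter
#' `rms / radius` exceeds `max_rms_ratio`, or when the fitted radius exceeds
#' `max_radius_m` — the quality gates that reject circles fitted across
#' branches (an arc through scattered branch returns tends to be either very
#' loose or implausibly wide). `dbh_cm = 200 * radius_m`.
#'
#' @param slice A [point_cloud()] (the breast-height slice).
#' @param tree One-row tree record with `x_m`, `y_m` (e.g., a
#'   [detect_treetops()] row).
#' @param search_radius_m Horizontal search radius around the stem (m).
#' @param min_points Minimum points for a usable fit.
#' @param max_rms_ratio Quality cap on `rms_m / radius_m`.
#' @param max_radius_m Largest credible stem radius (m); defaults to the
#'   search radius.
#' @return A `circle_fit` tibble with an extra `dbh_cm` column, or `NULL`
#'   when no acceptable fit exists (absence is a value, not an error).
#' @export
extract_dbh <- function(slice, tree, search_radius_m = 1.0, min_points = 10,
                        max_rms_ratio = 0.25,
                        max_radius_m = search_radius_m) {
  sl <- slice[slice$z_m >= 1.32 & slice$z_m <= 1.42, , drop = FALSE]
  d2 <- (sl$x_m - tree$x_m)^2 + (sl$y_m - tree$y_m)^2
  sl <- sl[d2 <= search_radius_m^2, , drop = FALSE]
  if (nrow(sl) < min_points) return(NULL)
  fit <- tryCatch(fit_circle_ls(cbind(sl$x_m, sl$y_m)),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$radius_m) || fit$radius_m <= 0) {
    return(NULL)
  }
  if (fit$rms_m / fit$radius_m > max_rms_ratio) return(NULL)
  if (fit$radius_m > max_radius_m) return(NULL)
  fit$dbh_cm <- 200 * fit$radius_m
  fit
}

#' Fit a height-diameter power model
#'
#' Nonlinear least squares of `dbh_cm = beta1 * height_m^beta2`, initialized
#' from the log-log linear fit and iterated to a relative parameter change
#' below `tol`. Reports the residual standard error
#' `sqrt(SSE / (n - 2))` and the parameter covariance matrix.
#'
#' @param heights Heights (m), positive.
#' @param dbhs DBH values (cm), positive, same length.
#' @param tol Relative-change convergence tolerance.
#' @param max_iter Iteration cap; non-convergence is an error.
#' @return An object of class `power_model` with elements `beta1`, `beta2`,
#'   `resid_se_cm`, `n`, `param_cov`.
#' @export
#' @examples
#' h <- seq(2, 25, length.out = 20)
#' fit_power_model(h, 4.29 * h^0.68)
fit_power_model <- function(heights, dbhs, tol = 1e-8, max_iter = 200) {
  if (length(heights) != length(dbhs) || length(heights) < 5) {
    ss_abort("need >= 5 height-DBH pairs.", "standscan_fit_error")
  }
  if (any(heights <= 0) || any(dbhs <= 0)) {
    ss_abort("heights and DBH values must be positive.",
             "standscan_fit_error")
  }
  ll <- lm(log(dbhs) ~ log(heights))
  b <- c(exp(coef(ll)[1]), coef(ll)[2])
  # Gauss-Newton with the stated convergence rule
  for (it in seq_len(max_iter)) {
    f <- b[1] * heights^b[2]
    res <- dbhs - f
    J <- cbind(heights^b[2], b[1] * heights^b[2] * log(heights))
    step <- tryCatch(qr.solve(J, res), error = function(e) NULL)
    if (is.null(step) || !all(is.finite(step))) {
      ss_abort("power-model fit is degenerate.", "standscan_fit_error")
    }
    # damped update to keep beta1 positive
    lam <- 1
    while (b[1] + lam * step[1] <= 0 && lam > 1e-8) lam <- lam / 2
    b_new <- b + lam * step
    rel <- max(abs(b_new - b) / pmax(abs(b), 1e-12))
    b <- b_new
    if (rel < tol) break
    if (it == max_iter) {
      ss_abort("power-model fit did not converge.", "standscan_fit_error")
    }
  }
  f <- b[1] * heights^b[2]
  res <- dbhs - f
  n <- length(heights)
  sse <- sum(res^2)
  resid_se <- sqrt(sse / (n - 2))
  J <- cbind(heights^b[2], b[1] * heights^b[2] * log(heights))
  JtJ_inv <- tryCatch(solve(crossprod(J)), error = function(e) {
    MASS::ginv(crossprod(J))
  })
  structure(list(beta1 = unname(b[1]), beta2 = unname(b[2]),
                 resid_se_cm = resid_se, n = n,
                 param_cov = resid_se^2 * JtJ_inv),
            class = "power_model")
}

#' Construct a power model from known coefficients
#'
#' Used to supply an externally fitted regional height-diameter model as
#' configuration (coefficients, residual SE, sample size, and optionally the
#' parameter covariance) rather than refitting it from data.
#'
#' @param beta1,beta2 Power-law parameters (> 0).
#' @param resid_se_cm Residual standard error (cm).
#' @param n Number of pairs behind the fit.
#' @param param_cov Optional 2x2 parameter covariance; defaults to zero
#'   (coefficients treated as known).
#' @return A `power_model`.
#' @export
power_model <- function(beta1, beta2, resid_se_cm, n,
                        param_cov = matrix(0, 2, 2)) {
  if (beta1 <= 0 || beta2 <= 0 || resid_se_cm < 0) {
    ss_abort("beta1, beta2 > 0 and resid_se_cm >= 0 required.",
             "standscan_parameter_error")
  }
  param_cov <- as.matrix(param_cov)
  if (any(dim(param_cov) != 2) ||
      max(abs(param_cov - t(param_cov))) > 1e-8 ||
      any(eigen(param_cov, symmetric = TRUE,
                only.values = TRUE)$values < -1e-8)) {
    ss_abort("param_cov must be symmetric positive semi-definite 2x2.",
             "standscan_parameter_error")
  }
  structure(list(beta1 = beta1, beta2 = beta2, resid_se_cm = resid_se_cm,
                 n = n, param_cov = param_cov), class = "power_model")
}

#' @export
print.power_model <- function(x, ...) {
  cat(sprintf(
    "<power_model> dbh_cm = %.4g * height_m^%.4g  (resid SE %.3g cm, n = %d)\n",
    x$beta1, x$beta2, x$resid_se_cm, x$n))
  invisible(x)
}

#' @export
predict.power_model <- function(object, height_m, ...) {
  object$beta1 * height_m^object$beta2
}

#' Prediction interval of a power model
#'
#' Two-sided interval expected to contain a *new* DBH observation at the
#' given height. The default is the t-based delta-method interval:
#' `fitted +/- t((1 + level)/2, n - 2) * sqrt(resid_se^2 + g' Cov g)` with
#' `g` the parameter gradient of the curve at that height. `method =
#' "monte_carlo"` instead propagates parameter uncertainty by sampling
#' coefficients from their Gaussian approximation and adding residual noise;
#' the two agree closely for well-conditioned fits.
#'
#' @param model A `power_model`.
#' @param height_m Height(s) at which to predict (m).
#' @param level Coverage level in (0, 1), default 0.90.
#' @param method `"delta"` (default) or `"monte_carlo"`.
#' @param n_sim Monte-Carlo draws.
#' @param seed Seed for the Monte-Carlo variant.
#' @return A tibble: `height_m`, `fit_cm`, `lo_cm`, `hi_cm`.
#' @export
prediction_interval <- function(model, height_m, level = 0.90,
                                method = c("delta", "monte_carlo"),
                                n_sim = 10000, seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(model, "power_model"))
  if (level <= 0 || level >= 1) {
    ss_abort("level must be in (0, 1).", "standscan_parameter_error")
  }
  if (model$n <= 2) {
    ss_abort("prediction interval needs n > 2.",
             "standscan_insufficient_data_error")
  }
  fit <- model$beta1 * height_m^model$beta2
  if (method == "delta") {
    g1 <- height_m^model$beta2
    g2 <- model$beta1 * height_m^model$beta2 * log(height_m)
    var_curve <- g1^2 * model$param_cov[1, 1] +
      2 * g1 * g2 * model$param_cov[1, 2] + g2^2 * model$param_cov[2, 2]
    half <- qt((1 + level) / 2, df = model$n - 2) *
      sqrt(model$resid_se_cm^2 + var_curve)
    tibble(height_m = height_m, fit_cm = fit, lo_cm = fit - half,
           hi_cm = fit + half)
  } else {
    with_seed(seed, {
      betas <- MASS::mvrnorm(n_sim, c(model$beta1, model$beta2),
                             model$param_cov)
      betas[, 1] <- pmax(betas[, 1], 1e-8)
      qs <- vapply(height_m, function(h) {
        draws <- betas[, 1] * h^betas[, 2] +
          rnorm(n_sim, 0, model$resid_se_cm)
        quantile(draws, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
      }, numeric(2))
      tibble(height_m = height_m, fit_cm = fit, lo_cm = qs[1, ],
             hi_cm = qs[2, ])
    })
  }
}

#' Filter height-DBH pairs by a regional model's prediction bounds
#'
#' Retains exactly the pairs whose DBH lies inside the two-sided prediction
#' interval of the supplied (regional) model at the pair's height; order is
#' preserved. This is the outlier gate that removes circle fits across
#' branches before a site model is fit.
#'
#' @param pairs A data frame with columns `height_m` and `dbh_cm`.
#' @param regional A `power_model`.
#' @param level Prediction level (default 0.90).
#' @return The retained subset of `pairs` (same columns, same order).
#' @export
filter_pairs_by_bounds <- function(pairs, regional, level = 0.90) {
  pairs <- as_tibble(pairs)
  if (nrow(pairs) == 0) return(pairs)
  pb <- prediction_interval(regional, pairs$height_m, level = level)
  keep <- pairs$dbh_cm >= pb$lo_cm & pairs$dbh_cm <= pb$hi_cm
  pairs[keep, , drop = FALSE]
}

#' Impute missing DBH values from a site model
#'
#' Trees without DBH receive the site model's fitted value
#' (`dbh_origin = "predicted"`); trees already carrying an extracted DBH are
#' never modified, so imputation is idempotent.
#'
#' @param plot A [tree_plot()].
#' @param site_model A `power_model` (typically fit from this plot's retained
#'   extracted pairs; a regional model may stand in when no site fit exists).
#' @return The plot with a complete `dbh_cm` column.
#' @export
impute_missing_dbh <- function(plot, site_model) {
  if (is.null(site_model)) {
    ss_abort("no site model and no regional fallback supplied.",
             "standscan_configuration_error")
  }
  stopifnot(inherits(site_model, "power_model"))
  miss <- is.na(plot$dbh_cm)
  out <- plot
  out$dbh_cm[miss] <- predict(site_model, plot$height_m[miss])
  out$dbh_origin[miss] <- "predicted"
  restamp_tree_plot(out, plot)
}

#' Extract, filter, and impute DBH for a detected tree list
#'
#' The full diameter workflow for one plot: circle-fit DBH extraction at each
#' detected stem, filtering of the extracted pairs against the regional
#' model's prediction bounds, a site power model fit from the retained pairs
#' (falling back to the regional model when too few pairs survive), and
#' imputation of all remaining DBH values. The extraction rate (fraction
#' of trees with `dbh_origin = "extracted"`) is recorded as an attribute
#' and message.
#'
#' @param plot A [tree_plot()] of detected trees (heights required).
#' @param slice A [point_cloud()] breast-height slice.
#' @param regional A `power_model` used for bound filtering and fallback.
#' @param level Prediction-bound level (default 0.90).
#' @param search_radius_m,min_points,max_rms_ratio Passed to [extract_dbh()].
#' @param quiet Suppress the extraction-rate message.
#' @return The plot with complete `dbh_cm` and `dbh_origin`; attributes
#'   `extraction_rate` and `site_model`.
#' @export
estimate_dbh <- function(plot, slice, regional, level = 0.90,
                         search_radius_m = 1.0, min_points = 10,
                         max_rms_ratio = 0.25, quiet = FALSE) {
  out <- plot
  out$dbh_cm <- NA_real_
  out$dbh_origin <- NA_character_
  fits <- purrr::map_dbl(seq_len(nrow(plot)), function(i) {
    f <- extract_dbh(slice, plot[i, ], search_radius_m = search_radius_m,
                     min_points = min_points, max_rms_ratio = max_rms_ratio)
    if (is.null(f)) NA_real_ else f$dbh_cm
  })
  pairs <- tibble(height_m = plot$height_m, dbh_cm = fits,
                  idx = seq_along(fits))
  pairs <- pairs[!is.na(pairs$dbh_cm), , drop = FALSE]
  kept <- filter_pairs_by_bounds(pairs, regional, level = level)
  out$dbh_cm[kept$idx] <- kept$dbh_cm
  out$dbh_origin[kept$idx] <- "extracted"
  site_model <- if (nrow(kept) >= 5) {
    tryCatch(fit_power_model(kept$height_m, kept$dbh_cm),
             error = function(e) regional)
  } else {
    regional
  }
  out <- impute_missing_dbh(restamp_tree_plot(out, plot), site_model)
  rate <- nrow(kept) / max(1, nrow(plot))
  if (!quiet) {
    message(sprintf("extracted DBH for %d/%d trees (%.1f%%)", nrow(kept),
                    nrow(plot), 100 * rate))
  }
  attr(out, "extraction_rate") <- rate
  attr(out, "site_model") <- site_model
  out
}
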