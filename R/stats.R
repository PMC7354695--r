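#' Coverage confidence ellipse of 2D points
#'
#' Fits the ellipse expected to contain `level` of the population under a
#' bivariate Gaussian model: centre at the arithmetic mean, axes from the
#' eigen-decomposition of the sample covariance scaled by
#' `sqrt(qchisq(level, df = 2))`.
#'
#' @param points two-column matrix/data.frame of (g, s) points.
#' @param level coverage level in (0, 1) (default 0.90).
#' @return object of class `ellipse_summary`; degenerate inputs (< 3
#'   points, or collinear) yield an object with `degenerate = TRUE` and no
#'   axes.
#' @export
confidence_ellipse <- function(points, level = 0.90) {
  if (level <= 0 || level >= 1) stop("`level` must be in (0, 1)")
  pts <- as.matrix(points)
  if (ncol(pts) != 2) stop("`points` must have two columns")
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  n <- nrow(pts)
  base <- list(n_points = n, level = level)
  if (n < 3) {
    return(structure(c(base, list(degenerate = TRUE,
                                  center = if (n) colMeans(pts) else c(NA, NA))),
                     class = "ellipse_summary"))
  }
  ctr <- colMeans(pts)
  cv <- stats::cov(pts)
  ev <- eigen(cv, symmetric = TRUE)
  if (min(ev$values) < 1e-14 * max(ev$values, 1e-300)) {
    return(structure(c(base, list(degenerate = TRUE, center = ctr,
                                  covariance = cv)),
                     class = "ellipse_summary"))
  }
  k <- sqrt(stats::qchisq(level, df = 2))
  structure(c(base, list(
    degenerate = FALSE,
    center = ctr,
    covariance = cv,
    semi_axes = k * sqrt(ev$values),
    orientation = atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  )), class = "ellipse_summary")
}

#' @export
print.ellipse_summary <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat(sprintf("degenerate ellipse (n = %d)\n", x$n_points))
  } else {
    cat(sprintf(
      "%.0f%% ellipse: centre (%.4f, %.4f), semi-axes %.4g / %.4g, angle %.2f rad, n = %d\n",
      100 * x$level, x$center[1], x$center[2],
      x$semi_axes[1], x$semi_axes[2], x$orientation, x$n_points))
  }
  invisible(x)
}

#' Test which points fall inside a confidence ellipse
#'
#' Mahalanobis criterion: a point is inside when its squared Mahalanobis
#' distance from the centre is at most `qchisq(level, 2)`.
#'
#' @param ellipse an `ellipse_summary`.
#' @param points two-column matrix of points.
#' @return logical vector.
#' @export
in_ellipse <- function(ellipse, points) {
  if (isTRUE(ellipse$degenerate)) stop("ellipse is degenerate")
  d2 <- stats::mahalanobis(as.matrix(points), ellipse$center,
                           ellipse$covariance)
  d2 <= stats::qchisq(ellipse$level, df = 2)
}

#' Euclidean shift between two condition ellipses
#'
#' Geometric distance between the ellipse centres, the headline measure of
#' a metabolic phasor shift between two conditions.
#'
#' @param a,b `ellipse_summary` objects (non-degenerate).
#' @return non-negative distance in phasor units.
#' @export
euclidean_shift <- function(a, b) {
  stopifnot(inherits(a, "ellipse_summary"), inherits(b, "ellipse_summary"))
  if (isTRUE(a$degenerate) || isTRUE(b$degenerate))
    stop("cannot compute a shift from a degenerate ellipse")
  sqrt(sum((a$center - b$center)^2))
}

#' Two-sided Mann-Whitney rank test
#'
#' Exact enumeration (via the exact null distribution of U) when both
#' groups have at most 8 observations and there are no ties; otherwise the
#' tie-corrected normal approximation with continuity correction.
#'
#' @param group_a,group_b numeric vectors (non-empty).
#' @return list with `U` (statistic for `group_a`), `p_value`, `exact`.
#' @export
rank_test <- function(group_a, group_b) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- length(group_a) <= 8 && length(group_b) <= 8 && !ties
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value, exact = exact)
}

#' Percent increment between two groups with propagated SE
#'
#' `100 (mean(stimulated) - mean(baseline)) / mean(baseline)`, the usual
#' fold-increment readout of stimulated vs basal intensity; the standard
#' error is propagated to first order from the two group SEs.
#'
#' @param baseline,stimulated numeric vectors; `mean(baseline)` must be
#'   positive.
#' @return list with `mean_percent` and `se_percent` (NA when a group has
#'   a single observation).
#' @export
percent_increment <- function(baseline, stimulated) {
  mb <- mean(baseline)
  if (!is.finite(mb) || mb <= 0) stop("baseline mean must be > 0")
  ms <- mean(stimulated)
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  se_b <- se(baseline); se_s <- se(stimulated)
  list(mean_percent = 100 * (ms - mb) / mb,
       se_percent = 100 * sqrt(se_s^2 / mb^2 + ms^2 * se_b^2 / mb^4))
}

#' Compare two conditions in phasor space
#'
#' Bundles the population comparison of two conditions: per-condition
#' confidence ellipses of the per-ROI mean phasors, the Euclidean distance
#' between their centres, and an optional rank test on a chosen scalar
#' column of the summaries.
#'
#' @param summary_a,summary_b per-ROI summary data.frames from
#'   [roi_phasor_summary()].
#' @param level ellipse coverage level.
#' @param test_column optional column name (e.g. `"mean_intensity"` or
#'   `"mean_f_bound"`) to compare with [rank_test()].
#' @return object of class `condition_comparison`.
#' @export
compare_conditions <- function(summary_a, summary_b, level = 0.90,
                               test_column = NULL) {
  ea <- confidence_ellipse(summary_a[, c("mean_g", "mean_s")], level)
  eb <- confidence_ellipse(summary_b[, c("mean_g", "mean_s")], level)
  res <- list(
    condition_a = summary_a$condition[1],
    condition_b = summary_b$condition[1],
    ellipse_a = ea, ellipse_b = eb,
    euclidean_distance = if (!ea$degenerate && !eb$degenerate)
      euclidean_shift(ea, eb) else NA_real_
  )
  if (!is.null(test_column)) {
    res$test_column <- test_column
    res$rank_test <- rank_test(summary_a[[test_column]],
                               summary_b[[test_column]])
  }
  structure(res, class = "condition_comparison")
}

#' @export
print.condition_comparison <- function(x, ...) {
  cat(sprintf("comparison %s vs %s: Euclidean shift %.5f phasor units\n",
              x$condition_a, x$condition_b, x$euclidean_distance))
  if (!is.null(x$rank_test))
    cat(sprintf("  Mann-Whitney on %s: U = %.1f, p = %.4g (%s)\n",
                x$test_column, x$rank_test$U, x$rank_test$p_value,
                if (x$rank_test$exact) "exact" else "normal approx."))
  invisible(x)
}
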