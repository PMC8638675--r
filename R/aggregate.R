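#' Kriging interpolation of cluster-level covariates to the grid
#'
#' Ordinary kriging with an exponential covariance and no nugget, the
#' conventional recipe for carrying survey-derived covariates onto a
#' prediction grid. The range parameter is set to the first quartile of
#' the pairwise inter-cluster distances (`range_rule = "q1"`). Proportion
#' inputs are logit-transformed before interpolation and predictions are
#' back-transformed to (0, 1).
#'
#' @param clusters Cluster table with `x_km`, `y_km`.
#' @param values Numeric vector of cluster-level covariate values.
#' @param grid Grid data.frame with `x_km`, `y_km`.
#' @param proportion If `TRUE` (default), `values` are proportions in
#'   (0, 1) and interpolation happens on the logit scale.
#' @param range_rule `"q1"` (first quartile of pairwise distances) or a
#'   positive number used directly as the range.
#' @return Numeric vector of interpolated values at the grid centroids.
#' @export
krige_covariate <- function(clusters, values, grid, proportion = TRUE,
                            range_rule = "q1") {
  coords <- as.matrix(clusters[, c("x_km", "y_km")])
  n <- nrow(coords)
  if (n < 3) stop("kriging needs at least 3 clusters", call. = FALSE)
  if (length(values) != n) stop("values must match the number of clusters", call. = FALSE)
  z <- values
  if (proportion) {
    if (any(values <= 0 | values >= 1))
      stop("proportion values must lie strictly in (0, 1); use proportion = FALSE for continuous covariates", call. = FALSE)
    z <- logit(values)
  }
  D <- as.matrix(stats::dist(coords))
  rng <- if (identical(range_rule, "q1")) {
    as.numeric(stats::quantile(D[upper.tri(D)], 0.25))
  } else as.numeric(range_rule)
  if (rng <= 0) stop("kriging range must be positive", call. = FALSE)
  C <- exp(-D / rng)
  Gx <- as.matrix(grid[, c("x_km", "y_km")])
  c0 <- exp(-cross_dist(coords, Gx) / rng)
  ## ordinary kriging system with the unbiasedness constraint
  A <- rbind(cbind(C, 1), c(rep(1, n), 0))
  B <- rbind(c0, 1)
  Wts <- solve(A, B)
  pred <- drop(crossprod(Wts[seq_len(n), , drop = FALSE], z))
  if (proportion) expit(pred) else pred
}

#' Population-weighted aggregation from grid to districts
#'
#' District values are population-weighted averages over grid cells whose
#' centroids fall within the district:
#' \eqn{x(A_i) \approx \sum_j x(s_j) q(s_j)}, where `q` are within-district
#' population shares summing to one.
#'
#' @param values Numeric vector over grid cells (for `district_covariate`).
#' @param grid Grid data.frame with `district_id` and population share `q`.
#' @return Named numeric vector of per-district values.
#' @export
district_covariate <- function(values, grid) {
  check_q(grid)
  if (length(values) != nrow(grid)) stop("values must match grid cells", call. = FALSE)
  out <- tapply(values * grid$q, grid$district_id, sum)
  out <- structure(as.numeric(out), names = names(out))
  out[order(as_district_order(names(out)))]
}

check_q <- function(grid) {
  stopifnot_named(grid, c("district_id", "q"), "grid")
  s <- tapply(grid$q, grid$district_id, sum)
  if (any(abs(s - 1) > 1e-8))
    stop("population shares q must sum to 1 within each district", call. = FALSE)
  invisible(TRUE)
}

as_district_order <- function(x) {
  suppressWarnings(n <- as.numeric(x))
  if (any(is.na(n))) order(x) else order(n)
}

#' Aggregate a posterior coverage surface to districts
#'
#' Applies the population-weighted average per posterior draw, preserving
#' the joint posterior structure:
#' \eqn{p_r(A_i) \approx \sum_j p_r(s_j)\, q(s_j)}.
#'
#' @param surface A `coverage_surface` from [predict_surface()], or a bare
#'   draws matrix (`m x n_cells`).
#' @param grid Grid data.frame with `district_id` and `q` (defaults to the
#'   surface's own grid).
#' @return Matrix `m x n_districts` of district coverage draws, columns
#'   named by district.
#' @export
aggregate_surface <- function(surface, grid = NULL) {
  if (inherits(surface, "coverage_surface")) {
    if (is.null(grid)) grid <- surface$grid
    draws <- surface$draws
  } else draws <- as.matrix(surface)
  check_q(grid)
  if (ncol(draws) != nrow(grid)) stop("draws do not match grid cells", call. = FALSE)
  ids <- unique(grid$district_id)[as_district_order(unique(as.character(grid$district_id)))]
  out <- sapply(ids, function(d) {
    idx <- grid$district_id == d
    drop(draws[, idx, drop = FALSE] %*% grid$q[idx])
  })
  out <- matrix(out, nrow = nrow(draws))
  colnames(out) <- as.character(ids)
  out
}

#' Exceedance probabilities for district coverage
#'
#' Posterior probability that district coverage attains each programmatic
#' threshold, estimated as the fraction of posterior draws at or above the
#' threshold. Defaults are the 80% and 95% coverage targets.
#'
#' @param district_draws Matrix `m x n_districts` of coverage draws.
#' @param thresholds Numeric thresholds in (0, 1).
#' @return Matrix `n_districts x length(thresholds)`, columns named
#'   `P(>=t)`.
#' @export
exceedance <- function(district_draws, thresholds = c(0.80, 0.95)) {
  district_draws <- as.matrix(district_draws)
  out <- sapply(thresholds, function(t) colMeans(district_draws >= t))
  out <- matrix(out, ncol = length(thresholds))
  colnames(out) <- sprintf("P(>=%.2f)", thresholds)
  rownames(out) <- colnames(district_draws)
  out
}

#' Posterior summaries of district coverage
#'
#' @param district_draws Matrix `m x n_districts` of coverage draws.
#' @param thresholds Exceedance thresholds.
#' @return data.frame with posterior mean, sd, 2.5/50/97.5 percent
#'   quantiles and exceedance probabilities per district.
#' @export
district_estimates <- function(district_draws, thresholds = c(0.80, 0.95)) {
  district_draws <- as.matrix(district_draws)
  qs <- t(apply(district_draws, 2, stats::quantile, c(0.025, 0.5, 0.975)))
  out <- data.frame(
    district_id = colnames(district_draws) %||% seq_len(ncol(district_draws)),
    mean = colMeans(district_draws),
    sd = apply(district_draws, 2, stats::sd),
    q025 = qs[, 1], median = qs[, 2], q975 = qs[, 3],
    row.names = NULL)
  cbind(out, exceedance(district_draws, thresholds))
}
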