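#' Normalize sampling weights within districts
#'
#' Scales the raw sampling weights so that, within each district, the
#' per-child normalized weights sum to the total number of children
#' surveyed in that district (\eqn{\sum_k \tilde w_{ki} = N_{A_i}}).
#' Relative weights are preserved, so the direct estimator is invariant to
#' any uniform rescaling of the raw weights.
#'
#' @param clusters A cluster table: one row per survey cluster with columns
#'   `district_id`, `n_children`, `n_vaccinated`, `weight` (and typically
#'   `cluster_id`, `x_km`, `y_km`, `stratum`).
#' @return The cluster table with an added per-child normalized weight
#'   column `w_norm`. Districts with zero surveyed children are dropped
#'   with a warning.
#' @export
normalize_weights <- function(clusters) {
  stopifnot_named(clusters, c("district_id", "n_children", "n_vaccinated", "weight"),
                  "cluster table")
  if (any(clusters$weight <= 0)) stop("weights must be > 0", call. = FALSE)
  tot <- tapply(clusters$n_children, clusters$district_id, sum)
  empty <- names(tot)[tot == 0]
  if (length(empty)) {
    warning(sprintf("dropping %d district(s) with zero surveyed children: %s",
                    length(empty), paste(empty, collapse = ", ")))
    clusters <- clusters[!clusters$district_id %in% empty, , drop = FALSE]
  }
  ## per-child weighted total within district: sum over clusters of w * N
  wsum <- tapply(clusters$weight * clusters$n_children, clusters$district_id, sum)
  nsum <- tapply(clusters$n_children, clusters$district_id, sum)
  id <- as.character(clusters$district_id)
  clusters$w_norm <- clusters$weight * as.numeric(nsum[id] / wsum[id])
  clusters
}

#' Design-based direct estimates of district coverage
#'
#' Computes, for every district, the Horvitz-Thompson ratio estimate
#' \eqn{\hat p^{DIR} = \sum_k \tilde w_{ki} Y_{ki} / \sum_k \tilde w_{ki}}
#' with its Taylor-linearized design variance (clusters as PSUs within
#' urban/rural strata, with-replacement approximation), the empirical-logit
#' transform \eqn{Y_L = \mathrm{logit}(\hat p^{DIR})} with known variance
#' \eqn{\hat\sigma^2_Y = \hat\sigma^2_{pDIR} / (\hat p(1-\hat p))^2}, and
#' the effective sample size \eqn{N_E = \hat p(1-\hat p)/\hat\sigma^2_{pDIR}}
#' with effective cases \eqn{Y_E = N_E \hat p}.
#'
#' Boundary districts (\eqn{\hat p \in \{0,1\}}) have undefined logit
#' variance and are flagged; their `y_logit`, `var_logit`, `n_eff`, `y_eff`
#' are `NA` and are treated as missing observations by the model fitters.
#' Strata containing a single cluster are collapsed with the other stratum
#' in the same district; a district with a single cluster overall gets an
#' `NA` variance.
#'
#' @param clusters Cluster table; normalized weights are computed if the
#'   `w_norm` column is absent.
#' @return A `data.frame` of class `direct_estimates` with one row per
#'   district: `district_id`, `n_clusters`, `n_raw`, `y_raw`, `p_hat_dir`,
#'   `var_p_dir`, `y_logit`, `var_logit`, `n_eff`, `y_eff`, `boundary_flag`.
#' @export
direct_estimates <- function(clusters) {
  if (is.null(clusters$w_norm)) clusters <- normalize_weights(clusters)
  if (is.null(clusters$stratum)) clusters$stratum <- "all"
  ids <- sort(unique(clusters$district_id))
  rows <- lapply(ids, function(d) {
    cl <- clusters[clusters$district_id == d, , drop = FALSE]
    est <- direct_estimate(cl)
    data.frame(district_id = d, n_clusters = nrow(cl),
               n_raw = sum(cl$n_children), y_raw = sum(cl$n_vaccinated),
               p_hat_dir = est[["p_hat_dir"]], var_p_dir = est[["var_p_dir"]])
  })
  out <- do.call(rbind, rows)
  out$boundary_flag <- out$p_hat_dir %in% c(0, 1)
  out <- empirical_logit(out)
  out <- effective_sample_size(out)
  class(out) <- c("direct_estimates", "data.frame")
  out
}

#' @rdname direct_estimates
#' @param clusters_in_district Cluster rows for one district (with
#'   `w_norm`).
#' @return For `direct_estimate()`: named vector `(p_hat_dir, var_p_dir)`.
#' @export
direct_estimate <- function(clusters_in_district) {
  cl <- clusters_in_district
  if (nrow(cl) < 1) stop("no clusters supplied", call. = FALSE)
  if (is.null(cl$w_norm)) stop("normalized weights (w_norm) required", call. = FALSE)
  if (is.null(cl$stratum)) cl$stratum <- "all"
  ## weighted cluster totals
  yw <- cl$w_norm * cl$n_vaccinated
  nw <- cl$w_norm * cl$n_children
  p_hat <- sum(yw) / sum(nw)
  if (nrow(cl) == 1) return(c(p_hat_dir = p_hat, var_p_dir = NA_real_))
  ## collapse single-PSU strata with the other stratum in the district
  counts <- table(cl$stratum)
  if (any(counts < 2)) cl$stratum <- "collapsed"
  z <- yw - p_hat * nw                  # linearized residual totals
  v <- 0
  for (h in unique(cl$stratum)) {
    idx <- cl$stratum == h
    nh <- sum(idx)
    zh <- z[idx]
    v <- v + nh / (nh - 1) * sum((zh - mean(zh))^2)
  }
  c(p_hat_dir = p_hat, var_p_dir = v / sum(nw)^2)
}

#' @rdname direct_estimates
#' @param direct A `direct_estimates` frame (or any data.frame with
#'   `p_hat_dir` and `var_p_dir`).
#' @export
empirical_logit <- function(direct) {
  p <- direct$p_hat_dir
  v <- direct$var_p_dir
  ok <- !is.na(p) & p > 0 & p < 1 & !is.na(v)
  direct$y_logit <- ifelse(ok, logit(p), NA_real_)
  direct$var_logit <- ifelse(ok, v / (p * (1 - p))^2, NA_real_)
  direct
}

#' @rdname direct_estimates
#' @export
effective_sample_size <- function(direct) {
  p <- direct$p_hat_dir
  v <- direct$var_p_dir
  ok <- !is.na(p) & p > 0 & p < 1 & !is.na(v) & v > 0
  direct$n_eff <- ifelse(ok, p * (1 - p) / v, NA_real_)
  direct$y_eff <- ifelse(ok, direct$n_eff * p, NA_real_)
  direct
}
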