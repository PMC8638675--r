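#' Leave-one-district-out data split
#'
#' For the discrete-area models the held-out district's responses are set
#' missing while its covariates are retained (the model then produces its
#' posterior predictive); for the continuous models all survey clusters
#' inside the district are dropped.
#'
#' @param data A district table (discrete) or cluster table (continuous).
#' @param district_i District id to hold out.
#' @param type `"discrete"` or `"continuous"`.
#' @return The training data with district `district_i` masked or removed.
#' @export
lodo_split <- function(data, district_i, type = c("discrete", "continuous")) {
  type <- match.arg(type)
  if (length(unique(data$district_id)) < 3)
    stop("leave-one-district-out needs at least 3 districts", call. = FALSE)
  if (!district_i %in% data$district_id)
    stop("unknown district id", call. = FALSE)
  if (type == "continuous")
    return(data[data$district_id != district_i, , drop = FALSE])
  out <- data
  idx <- out$district_id == district_i
  for (col in intersect(c("y_raw", "n_raw", "y_logit", "var_logit",
                          "n_eff", "y_eff"), names(out)))
    out[[col]][idx] <- NA
  out
}

#' Cross-validation comparison metrics
#'
#' The four scores used to compare held-out district predictions
#' \eqn{\hat p_i} with the reference values \eqn{p_i} (the direct survey
#' estimates): relative bias \eqn{\frac{1}{n_A}\sum_i (\hat p_i -
#' p_i)/p_i}, root mean square error, mean absolute error, and the
#' continuous ranked probability score
#' \eqn{\mathrm{CRPS}(F_i, p_i) = E|X_i - p_i| - \frac12 E|X_i - X_i^*|}
#' estimated from posterior draws by the exact double-sum estimator (an
#' O(m log m) sorted form is used; it equals the double sum to numerical
#' precision).
#'
#' @param p_hat Predicted values (posterior means of held-out coverage).
#' @param p Reference values, all positive for `metric_rbias`.
#' @return `metric_rbias`: scalar; `metric_rmse_mae`: named vector
#'   `c(rmse =, mae =)`; `metric_crps`: scalar (one district; callers
#'   average over districts).
#' @export
metric_rbias <- function(p_hat, p) {
  stopifnot(length(p_hat) == length(p))
  if (any(p <= 0)) stop("reference values must be positive for relative bias", call. = FALSE)
  mean((p_hat - p) / p)
}

#' @rdname metric_rbias
#' @export
metric_rmse_mae <- function(p_hat, p) {
  stopifnot(length(p_hat) == length(p))
  e <- p_hat - p
  c(rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
}

#' @rdname metric_rbias
#' @param draws Posterior draws of held-out coverage for one district.
#' @param p_i Reference value for that district.
#' @param method `"sorted"` (default, O(m log m)) or `"double"` (explicit
#'   O(m^2) double sum).
#' @export
metric_crps <- function(draws, p_i, method = c("sorted", "double")) {
  method <- match.arg(method)
  m <- length(draws)
  if (m < 2) stop("CRPS needs at least 2 draws", call. = FALSE)
  t1 <- mean(abs(draws - p_i))
  if (method == "double") {
    t2 <- sum(abs(outer(draws, draws, "-"))) / (2 * m^2)
  } else {
    x <- sort(draws)
    ## sum_{j,k} |x_j - x_k| = 2 * sum_i (2i - m - 1) x_(i)
    t2 <- sum((2 * seq_len(m) - m - 1) * x) / m^2
  }
  t1 - t2
}

#' Leave-one-district-out model comparison
#'
#' Runs the full cross-validation study on a synthetic country: computes
#' design-based direct estimates, prepares district- and cluster-level
#' covariates (population-weighted aggregation and grid lookup), and for
#' every requested model refits with each district held out in turn,
#' scoring the held-out posterior against the direct estimate
#' \eqn{\hat p^{DIR}_i} with RBias, RMSE, MAE and CRPS. Districts whose
#' direct estimate is on the boundary (undefined reference variance) are
#' excluded from the metric averages and counted. A constant
#' national-mean predictor (mean of the other districts' direct
#' estimates) is scored alongside as a baseline.
#'
#' @param country A `synthetic_country` from [generate_country()].
#' @param models Subset of `c("dunwb", "dln", "dess", "cgpiid", "cgp")`.
#' @param covariates `"with"`, `"without"`, or both.
#' @param seed Integer seed for all model fits.
#' @param control_discrete,control_gp [mcmc_control()] settings for the
#'   refits; defaults are sized for a cross-validation loop.
#' @param n_draws_pred Posterior draws propagated to held-out district
#'   predictions for the continuous models.
#' @return Object of class `coverage_cv`: `table` (model x covariates x
#'   metrics, plus the baseline row), `excluded` (boundary district
#'   count), and per-model held-out predictions.
#' @export
run_comparison <- function(country,
                           models = c("dunwb", "dln", "dess", "cgpiid", "cgp"),
                           covariates = "with",
                           seed = 1,
                           control_discrete = mcmc_control(n_chains = 2, n_iter = 600,
                                                           n_warmup = 600),
                           control_gp = mcmc_control(n_chains = 1, n_iter = 600,
                                                     n_warmup = 600),
                           n_draws_pred = 100) {
  stopifnot(inherits(country, "synthetic_country"))
  covariates <- match.arg(covariates, c("with", "without"), several.ok = TRUE)
  clusters <- normalize_weights(country$clusters)
  direct <- direct_estimates(clusters)
  grid <- country$grid
  cov_names <- country$config$covariates

  ## district-level covariates by population-weighted aggregation,
  ## cluster-level covariates by grid-cell lookup
  for (nm in cov_names) {
    direct[[nm]] <- as.numeric(district_covariate(grid[[nm]], grid))
    clusters[[nm]] <- grid_lookup(grid, clusters$x_km, clusters$y_km, nm)
  }

  usable <- !direct$boundary_flag & !is.na(direct$var_p_dir) & direct$var_p_dir > 0
  p_ref <- direct$p_hat_dir
  ids <- direct$district_id
  n_A <- length(ids)

  rows <- list(); heldout <- list()
  for (cv_set in covariates) {
    form <- if (cv_set == "with" && length(cov_names))
      stats::as.formula(paste("~", paste(cov_names, collapse = "+"))) else ~1
    for (mod in models) {
      pred_mean <- rep(NA_real_, n_A)
      pred_draws <- vector("list", n_A)
      for (i in seq_len(n_A)) {
        if (!usable[i]) next
        if (mod %in% c("dunwb", "dln", "dess")) {
          train <- lodo_split(direct, ids[i], "discrete")
          fit <- switch(mod,
            dunwb = fit_dunwb(train, country$W, form, seed = substream_seed(seed, paste0("cv", mod, i)), control = control_discrete),
            dln = fit_dln(train, country$W, form, seed = substream_seed(seed, paste0("cv", mod, i)), control = control_discrete),
            dess = fit_dess(train, country$W, form, seed = substream_seed(seed, paste0("cv", mod, i)), control = control_discrete))
          pred_draws[[i]] <- fit$draws$p[, i]
        } else {
          train <- lodo_split(clusters, ids[i], "continuous")
          fit <- fit_gp(train, form, model = mod,
                        seed = substream_seed(seed, paste0("cv", mod, i)),
                        control = control_gp)
          gsub_i <- grid[grid$district_id == ids[i], , drop = FALSE]
          surf <- predict_surface(fit, gsub_i, n_draws = n_draws_pred,
                                  seed = substream_seed(seed, paste0("cvp", mod, i)))
          pred_draws[[i]] <- drop(surf$draws %*% gsub_i$q)
        }
        pred_mean[i] <- mean(pred_draws[[i]])
      }
      ok <- usable & !is.na(pred_mean)
      rm2 <- metric_rmse_mae(pred_mean[ok], p_ref[ok])
      crps <- mean(mapply(function(d, p) metric_crps(d, p),
                          pred_draws[ok], p_ref[ok]))
      rows[[length(rows) + 1]] <- data.frame(
        model = model_label(mod), covariates = cv_set,
        RMSE = unname(rm2["rmse"]),
        RBias = metric_rbias(pred_mean[ok], p_ref[ok]),
        MAE = unname(rm2["mae"]), CRPS = crps)
      heldout[[paste(mod, cv_set, sep = ".")]] <-
        list(pred_mean = pred_mean, draws = pred_draws)
    }
  }
  ## constant national-mean baseline
  base_pred <- sapply(seq_len(n_A), function(i) mean(p_ref[usable & ids != ids[i]]))
  okb <- usable
  rmb <- metric_rmse_mae(base_pred[okb], p_ref[okb])
  rows[[length(rows) + 1]] <- data.frame(
    model = "national-mean", covariates = "-",
    RMSE = unname(rmb["rmse"]), RBias = metric_rbias(base_pred[okb], p_ref[okb]),
    MAE = unname(rmb["mae"]), CRPS = NA_real_)
  structure(list(table = do.call(rbind, rows),
                 excluded = sum(!usable),
                 district_id = ids, reference = p_ref, usable = usable,
                 heldout = heldout, seed = seed),
            class = "coverage_cv")
}

model_label <- function(m) {
  switch(m, dunwb = "D-UNWB", dln = "D-LN", dess = "D-ESS",
         cgpiid = "C-GPIID", cgp = "C-GP", m)
}

#' Look up grid-cell values at point locations
#'
#' Returns the value of a grid column at the cell whose centroid is
#' nearest to each point (survey clusters sit on cell centroids).
#'
#' @param grid Grid data.frame with `x_km`, `y_km`.
#' @param x,y Point coordinates (km).
#' @param col Grid column name.
#' @return Vector of looked-up values.
#' @export
grid_lookup <- function(grid, x, y, col) {
  gx <- grid$x_km; gy <- grid$y_km
  idx <- vapply(seq_along(x), function(i)
    which.min((gx - x[i])^2 + (gy - y[i])^2), integer(1))
  grid[[col]][idx]
}

#' @export
print.coverage_cv <- function(x, digits = 3, ...) {
  cat("Leave-one-district-out model comparison\n")
  if (x$excluded > 0)
    cat(sprintf("  (%d district(s) with boundary/degenerate direct estimates excluded)\n",
                x$excluded))
  tab <- x$table
  tab[, c("RMSE", "RBias", "MAE", "CRPS")] <-
    round(tab[, c("RMSE", "RBias", "MAE", "CRPS")], digits)
  print(tab, row.names = FALSE)
  invisible(x)
}
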