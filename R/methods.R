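#' Unified model-fitting interface
#'
#' Front-end dispatching to the three discrete-area fitters
#' ([fit_dunwb()], [fit_dln()], [fit_dess()]) or the continuous
#' geostatistical fitter ([fit_gp()]), all of which return a
#' `coverage_fit` object supporting `print`, `summary`, `coef`,
#' `predict`, `plot`, `residuals` and `simulate`.
#'
#' @param formula RHS-only covariate formula, e.g. `~ remoteness`.
#' @param data District table (discrete models; see [direct_estimates()])
#'   or cluster table (continuous models).
#' @param model One of `"dunwb"`, `"dln"`, `"dess"`, `"cgpiid"`, `"cgp"`.
#' @param graph Binary adjacency matrix (discrete models).
#' @param seed Integer seed.
#' @param control An [mcmc_control()].
#' @param ... Passed to the underlying fitter.
#' @return A `coverage_fit`.
#' @export
fit_coverage <- function(formula = ~1, data, model, graph = NULL, seed = 1,
                         control = mcmc_control(), ...) {
  model <- match.arg(model, c("dunwb", "dln", "dess", "cgpiid", "cgp"))
  if (model %in% c("dunwb", "dln", "dess")) {
    if (is.null(graph)) stop("discrete models need an adjacency matrix (graph)", call. = FALSE)
    switch(model,
           dunwb = fit_dunwb(data, graph, formula, seed = seed, control = control, ...),
           dln = fit_dln(data, graph, formula, seed = seed, control = control, ...),
           dess = fit_dess(data, graph, formula, seed = seed, control = control, ...))
  } else {
    fit_gp(data, formula, model = model, seed = seed, control = control, ...)
  }
}

#' @export
print.coverage_fit <- function(x, ...) {
  m <- nrow(x$draws$beta)
  cat(sprintf("%s coverage model fit (%d posterior draws, %d chain%s)\n",
              x$model_id, m, x$control$n_chains,
              if (x$control$n_chains > 1) "s" else ""))
  cat(sprintf("  units: %d %s; covariates: %s\n",
              if (x$kind == "discrete") nrow(x$X) else nrow(x$coords),
              if (x$kind == "discrete") "districts" else "clusters",
              paste(colnames(x$X), collapse = ", ")))
  if (x$kind == "discrete" && any(!x$observed))
    cat(sprintf("  %d district(s) missing (posterior-predictive imputed)\n",
                sum(!x$observed)))
  cat(sprintf("  converged (split-Rhat < %.2f): %s\n",
              x$control$rhat_threshold, x$converged))
  cat("  coefficients (posterior means):\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.coverage_fit <- function(object, ...) {
  colMeans(object$draws$beta)
}

#' @export
summary.coverage_fit <- function(object, ...) {
  d <- object$draws
  pars <- list(); nm <- character(0)
  add <- function(v, name) {
    pars[[length(pars) + 1]] <<- v; nm[length(nm) + 1] <<- name
  }
  for (j in seq_len(ncol(d$beta))) add(d$beta[, j], colnames(d$beta)[j])
  if (object$kind == "discrete") {
    add(d$rho, "rho"); add(d$sigma2_phi, "sigma2_phi")
  } else {
    add(d$sigma_omega, "sigma_omega"); add(d$range_km, "range_km")
    if (!is.null(d$sigma_eps)) add(d$sigma_eps, "sigma_eps")
  }
  tab <- t(vapply(pars, function(v)
    c(mean = mean(v), sd = stats::sd(v),
      stats::quantile(v, c(0.025, 0.5, 0.975)), n_eff = ess_basic(v)),
    numeric(6)))
  rownames(tab) <- nm
  out <- list(model_id = object$model_id, table = tab,
              converged = object$converged,
              max_rhat = suppressWarnings(max(object$diagnostics$rhat, na.rm = TRUE)))
  class(out) <- "summary.coverage_fit"
  out
}

#' @export
print.summary.coverage_fit <- function(x, ...) {
  cat(sprintf("%s posterior summary (max split-Rhat %.3f, converged: %s)\n",
              x$model_id, x$max_rhat, x$converged))
  print(round(x$table, 4))
  invisible(x)
}

#' Posterior district estimates or surface predictions from a fit
#'
#' For discrete fits, returns the district-level posterior summary table
#' (mean, sd, quantiles, exceedance probabilities). For continuous fits
#' with `newdata` a grid, predicts the coverage surface (see
#' [predict_surface()]) and, when the grid carries population shares `q`,
#' also aggregates to district draws.
#'
#' @param object A `coverage_fit`.
#' @param newdata Grid data.frame (continuous fits); ignored for discrete
#'   fits.
#' @param thresholds Exceedance thresholds for district summaries.
#' @param type `"district"` (default) or `"surface"` (continuous only).
#' @param n_draws,seed Passed to [predict_surface()].
#' @param ... Unused.
#' @export
predict.coverage_fit <- function(object, newdata = NULL,
                                 thresholds = c(0.80, 0.95),
                                 type = c("district", "surface"),
                                 n_draws = 100, seed = 1, ...) {
  type <- match.arg(type)
  if (object$kind == "discrete") {
    draws <- object$draws$p
    colnames(draws) <- as.character(object$district_id %||% seq_len(ncol(draws)))
    return(district_estimates(draws, thresholds))
  }
  if (is.null(newdata)) stop("continuous fits need a prediction grid (newdata)", call. = FALSE)
  surf <- predict_surface(object, newdata, n_draws = n_draws, seed = seed)
  if (type == "surface" || is.null(newdata$q)) return(surf)
  district_estimates(aggregate_surface(surf, newdata), thresholds)
}

#' @export
residuals.coverage_fit <- function(object, ...) {
  p_mean <- colMeans(object$draws$p)
  r <- object$response
  obs <- if (object$kind == "continuous") r$y / r$n
  else if (object$model_id == "D-LN") expit(r$y)
  else r$y / r$n
  obs - p_mean
}

#' Posterior-predictive simulation from a fitted model
#'
#' Draws replicate responses from the fitted sampling distribution, one
#' replicate per (thinned) posterior draw: binomial counts for D-UNWB /
#' D-ESS / the continuous models, Gaussian empirical logits for D-LN.
#'
#' @param object A `coverage_fit` (the fitters store the response
#'   internally via their draws; counts must be supplied for discrete
#'   models through `nsim`-long recycling of the stored design).
#' @param nsim Number of replicates.
#' @param seed Integer seed.
#' @param newdata The data the model was fitted to (district table or
#'   cluster table); required to recover the sampling denominators.
#' @param ... Unused.
#' @return Matrix `nsim x n_units` of simulated responses.
#' @export
simulate.coverage_fit <- function(object, nsim = 100, seed = 1,
                                  newdata = NULL, ...) {
  if (is.null(newdata))
    stop("supply the fitted data via newdata to recover sampling denominators", call. = FALSE)
  set.seed(substream_seed(seed, "simulate"))
  m <- nrow(object$draws$p)
  idx <- unique(round(seq(1, m, length.out = min(nsim, m))))
  if (object$kind == "continuous") {
    n <- newdata$n_children
    out <- t(vapply(idx, function(k)
      stats::rbinom(length(n), n, object$draws$p[k, ]), numeric(length(n))))
  } else if (object$model_id == "D-LN") {
    v <- newdata$var_logit
    out <- t(vapply(idx, function(k)
      stats::rnorm(length(v), object$draws$eta[k, ], sqrt(ifelse(is.na(v), 0, v))),
      numeric(length(v))))
  } else {
    n <- if (object$model_id == "D-ESS") round(newdata$n_eff) else newdata$n_raw
    n2 <- ifelse(is.na(n), 0L, as.integer(n))
    out <- t(vapply(idx, function(k)
      stats::rbinom(length(n2), n2, object$draws$p[k, ]), numeric(length(n2))))
  }
  out
}

#' Map a fitted model's district estimates
#'
#' Chloropleth of posterior mean coverage over the district polygons
#' (discrete fits or aggregated continuous estimates). Falls back to a
#' dot plot of estimates with 95% intervals when no polygons are given.
#'
#' @param x A `coverage_fit`.
#' @param districts District data.frame with a `polygon` list-column (e.g.
#'   from [generate_country()]); optional.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.coverage_fit <- function(x, districts = NULL, ...) {
  if (x$kind == "discrete") {
    est <- predict(x)
  } else {
    stop("plot the surface via predict(fit, grid, type = 'surface') and plot_surface()", call. = FALSE)
  }
  if (!is.null(districts) && !is.null(districts$polygon)) {
    cols <- grDevices::hcl.colors(100, "viridis")
    rng <- range(est$mean)
    idx <- pmin(100, pmax(1, 1 + floor(99 * (est$mean - rng[1]) / max(1e-12, diff(rng)))))
    xs <- range(unlist(lapply(districts$polygon, function(p) p[, 1])))
    ys <- range(unlist(lapply(districts$polygon, function(p) p[, 2])))
    graphics::plot(NA, xlim = xs, ylim = ys, asp = 1, xlab = "km", ylab = "km",
                   main = sprintf("%s posterior mean coverage", x$model_id), ...)
    for (i in seq_len(nrow(districts)))
      graphics::polygon(districts$polygon[[i]], col = cols[idx[i]], border = "grey30")
  } else {
    o <- order(est$mean)
    graphics::plot(est$mean[o], seq_along(o), xlim = c(0, 1), pch = 19,
                   xlab = "coverage", ylab = "district (sorted)",
                   main = sprintf("%s district estimates", x$model_id), ...)
    graphics::segments(est$q025[o], seq_along(o), est$q975[o], seq_along(o))
  }
  invisible(est)
}
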