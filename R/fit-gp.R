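#' Fit the continuous geostatistical coverage models
#'
#' Binomial cluster-level models with a Matern (nu = 1) Gaussian-process
#' spatial random effect:
#' \deqn{Y(s_i) \sim \mathrm{Binomial}(N(s_i), p(s_i)),\quad
#'   \mathrm{logit}\, p(s_i) = x(s_i)'\beta + \omega(s_i) [+ \epsilon(s_i)],}
#' where `model = "cgpiid"` includes the iid nugget
#' \eqn{\epsilon(s_i) \sim N(0, \sigma^2_\epsilon)} for between-cluster
#' (excess binomial) variation and `model = "cgp"` omits it. The
#' covariance parameters \eqn{(r, \sigma_\omega)} carry a joint penalized
#' complexity prior and \eqn{\sigma_\epsilon} an exponential PC prior (see
#' [pc_prior_spec()]); by default the range threshold `r0` is 5% of the
#' north-south extent of the cluster locations.
#'
#' Inference uses exact dense-covariance MCMC at desk scale: the latent
#' field is whitened (\eqn{\omega = \sigma_\omega L(r)\nu}) and the
#' jointly-Gaussian block \eqn{(\beta, \nu, \delta)} is updated by
#' elliptical slice sampling, while \eqn{(\log\sigma_\omega, \log r
#' [, \log\sigma_\epsilon])} moves by adaptive random-walk Metropolis with
#' the Cholesky factor recomputed per proposal.
#'
#' @param clusters Cluster table with `x_km`, `y_km`, `n_children`,
#'   `n_vaccinated` and any covariate columns used by `formula`.
#' @param formula RHS-only covariate formula (default intercept only).
#' @param model `"cgpiid"` (with nugget) or `"cgp"` (without).
#' @param pc A [pc_prior_spec()]; `NULL` uses `r0 = 0.05 *` north-south
#'   extent of the data.
#' @param beta_var Prior variance of regression coefficients.
#' @param seed Integer seed.
#' @param control An [mcmc_control()].
#' @return Object of class `coverage_fit` with draw matrices `beta`,
#'   `omega` (at data locations), `sigma_omega`, `range_km`, `sigma_eps`
#'   (nugget model only), `eta`, `p`, plus diagnostics and coordinates.
#' @export
fit_gp <- function(clusters, formula = ~1, model = c("cgpiid", "cgp"),
                   pc = NULL, beta_var = 1e6, seed = 1,
                   control = mcmc_control()) {
  model <- match.arg(model)
  stopifnot_named(clusters, c("x_km", "y_km", "n_children", "n_vaccinated"),
                  "cluster table")
  coords <- as.matrix(clusters[, c("x_km", "y_km")])
  n <- nrow(coords)
  if (n < 2) stop("at least two clusters are required", call. = FALSE)
  if (is.null(pc)) {
    ns_extent <- diff(range(coords[, 2]))
    if (ns_extent <= 0) ns_extent <- diff(range(coords[, 1]))
    pc <- pc_prior_spec(r0 = 0.05 * ns_extent)
  }
  X <- stats::model.matrix(formula, clusters)
  sc <- standardize_X(X)
  Xs <- sc$X
  p <- ncol(X)
  y <- clusters$n_vaccinated; Nn <- clusters$n_children
  if (any(y > Nn)) stop("n_vaccinated exceeds n_children", call. = FALSE)
  D <- as.matrix(stats::dist(coords))
  nugget <- model == "cgpiid"
  b_sd <- sqrt(beta_var)

  ## stable binomial log-likelihood: y*eta - n*log(1 + exp(eta))
  loglik_eta <- function(eta)
    sum(y * eta - Nn * (pmax(eta, 0) + log1p(exp(-abs(eta)))))

  j0 <- if (any(sc$const)) which(sc$const)[1] else NA_integer_
  chains <- lapply(seq_len(control$n_chains), function(ch) {
    set.seed(substream_seed(seed, paste0("gp-", model, "-chain", ch)))
    run_gp_chain(loglik_eta, Xs, D, pc, nugget, b_sd, control, j0)
  })

  beta <- unstandardize_beta(combine_chains(chains, "beta"), sc)
  colnames(beta) <- colnames(X)
  eta <- combine_chains(chains, "eta")
  hyper_names <- c("beta", "hyper", "eta")
  diag_tab <- rhat_table(chains, hyper_names)
  th <- combine_chains(chains, "theta")
  fit <- structure(list(
    model_id = toupper(sub("cgpiid", "C-GPIID", sub("^cgp$", "C-GP", model))),
    draws = list(beta = beta,
                 omega = combine_chains(chains, "omega"),
                 sigma_omega = exp(th[, 1]),
                 range_km = exp(th[, 2]),
                 sigma_eps = if (nugget) exp(th[, 3]) else NULL,
                 eta = eta, p = expit(eta)),
    diagnostics = diag_tab,
    converged = all(is.na(diag_tab$rhat) |
                      diag_tab$rhat < control$rhat_threshold),
    response = list(y = y, n = Nn),
    coords = coords, X = X, formula = formula, scaling = sc, pc = pc,
    nugget = nugget, seed = seed, control = control, kind = "continuous"
  ), class = "coverage_fit")
  fit
}

## Whitened latent field: omega = sigma_omega * L(r)' nu with nu ~ N(0, I)
## (and delta ~ N(0, I) for the nugget). nu/delta move by elliptical slice
## sampling; (beta, log sigma_omega, log r [, log sigma_eps]) move by
## per-coordinate adaptive Metropolis, recomputing the Cholesky factor only
## when the range coordinate is proposed.
run_gp_chain <- function(loglik_eta, Xs, D, pc, nugget, b_sd, control,
                         j0 = NA_integer_) {
  n <- nrow(D); p <- ncol(Xs)
  n_tot <- control$n_warmup + control$n_iter
  ## x = (beta, log sigma_omega, log range [, log sigma_eps])
  x <- c(rep(0, p), log(0.5), log(4 * pc$r0), if (nugget) log(0.3))
  j_sig <- p + 1; j_rng <- p + 2; j_eps <- if (nugget) p + 3
  d_x <- length(x)
  corr_of <- corr_builder(D)
  R_corr <- chol_jitter(corr_of(exp(x[j_rng])), 1)
  ## state kept on the centered scale (omega, eps) so elliptical-slice
  ## likelihood evaluations are plain vector sums; hyperparameter moves act
  ## in the whitened representation nu = L^{-1} omega / sigma (prior N(0,I)),
  ## mapping the field deterministically through proposed (sigma, r)
  omega <- rep(0, n)
  eps <- if (nugget) rep(0, n) else 0
  eta_of <- function(b, omega, eps) drop(Xs %*% b) + omega + eps
  log_prior_x <- function(x)
    sum(stats::dnorm(x[seq_len(p)], 0, b_sd, log = TRUE)) +
    pc_prior_logdensity(exp(x[j_rng]), exp(x[j_sig]), pc,
                        if (nugget) exp(x[j_eps])) +
    sum(x[(p + 1):d_x])                  # log-scale jacobians
  lstep <- rep(log(0.15), d_x)
  lstep_t <- log(0.3)
  lstep_d <- log(0.3)
  lstep_cs <- log(0.3)
  lstep_ce <- log(0.3)
  keep <- control$n_iter
  out <- list(beta = matrix(NA_real_, keep, p),
              omega = matrix(NA_real_, keep, n),
              eta = matrix(NA_real_, keep, n),
              theta = matrix(NA_real_, keep, d_x - p),
              hyper = matrix(NA_real_, keep, d_x - p))
  for (it in seq_len(n_tot)) {
    b <- x[seq_len(p)]
    sig <- exp(x[j_sig])
    ## elliptical slice updates of the field (and nugget effects)
    loglik_om <- function(v) loglik_eta(eta_of(b, v, eps))
    for (s in seq_len(control$n_ess)) {
      up <- ess_update(omega, sig * drop(crossprod(R_corr, stats::rnorm(n))),
                       loglik_om)
      omega <- up$f
    }
    if (nugget) {
      loglik_eps <- function(v) loglik_eta(eta_of(b, omega, v))
      for (s in seq_len(control$n_ess)) {
        up <- ess_update(eps, exp(x[j_eps]) * stats::rnorm(n), loglik_eps)
        eps <- up$f
      }
    }
    ## whiten once per iteration for the hyperparameter proposals
    nu <- backsolve(R_corr, omega, transpose = TRUE) / sig
    delta <- if (nugget) eps / exp(x[j_eps]) else 0
    lp <- loglik_eta(eta_of(b, omega, eps)) + log_prior_x(x)
    propose <- function(prop, lstep_j) {
      R_prop <- R_corr
      om_prop <- omega; ep_prop <- eps
      if (prop[j_rng] != x[j_rng]) {
        R_prop <- tryCatch(chol_jitter(corr_of(exp(prop[j_rng])), 1),
                           error = function(e) NULL)
        if (is.null(R_prop)) return(NULL)
        om_prop <- exp(prop[j_sig]) * drop(crossprod(R_prop, nu))
      } else if (prop[j_sig] != x[j_sig]) {
        om_prop <- omega * exp(prop[j_sig] - x[j_sig])
      }
      if (nugget && prop[j_eps] != x[j_eps])
        ep_prop <- eps * exp(prop[j_eps] - x[j_eps])
      lp_prop <- loglik_eta(eta_of(prop[seq_len(p)], om_prop, ep_prop)) +
        log_prior_x(prop)
      list(x = prop, lp = lp_prop, R = R_prop, omega = om_prop, eps = ep_prop)
    }
    accept <- function(cand, alpha) {
      if (!is.null(cand) && is.finite(cand$lp) && stats::runif(1) < alpha) {
        x <<- cand$x; lp <<- cand$lp; R_corr <<- cand$R
        omega <<- cand$omega; eps <<- cand$eps; b <<- x[seq_len(p)]
        TRUE
      } else FALSE
    }
    ## per-coordinate MH on (beta, theta); the range coordinate and the
    ## joint ridge move below each require a fresh correlation Cholesky,
    ## so they alternate between iterations
    for (j in seq_len(d_x)) {
      if (j == j_rng && it %% 2 == 1) next
      prop <- x
      prop[j] <- prop[j] + exp(lstep[j]) * stats::rnorm(1)
      cand <- propose(prop, lstep[j])
      alpha <- if (is.null(cand) || !is.finite(cand$lp)) 0
               else min(1, exp(cand$lp - lp))
      accept(cand, alpha)
      if (it <= control$n_warmup)
        lstep[j] <- lstep[j] + (alpha - 0.44) / max(1, it)^0.6
    }
    ## joint move along the sigma_omega-range ridge (strongly correlated
    ## under infill asymptotics for Matern nu = 1)
    if (it %% 2 == 1) {
      s <- exp(lstep_d) * stats::rnorm(1)
      prop <- x
      prop[j_sig] <- prop[j_sig] + s
      prop[j_rng] <- prop[j_rng] + s
      cand <- propose(prop, lstep_d)
      alpha <- if (is.null(cand) || !is.finite(cand$lp)) 0
               else min(1, exp(cand$lp - lp))
      accept(cand, alpha)
      if (it <= control$n_warmup)
        lstep_d <- lstep_d + (alpha - 0.44) / max(1, it)^0.6
    }
    ## interweaved centered-parameterization updates of the scale
    ## parameters: given the field, sigma_omega (resp. sigma_eps) has a
    ## cheap conditional that does not touch the likelihood, which breaks
    ## the residual autocorrelation the whitened moves leave behind
    {
      nu_cur <- backsolve(R_corr, omega, transpose = TRUE)
      q_om <- sum(nu_cur^2)              # omega' C^{-1} omega
      ls_cur <- x[j_sig]
      ls_prop <- ls_cur + exp(lstep_cs) * stats::rnorm(1)
      tgt <- function(ls) -n * ls - q_om / (2 * exp(2 * ls)) -
        pc$lambda_sigma * exp(ls) + ls
      alpha <- min(1, exp(tgt(ls_prop) - tgt(ls_cur)))
      if (stats::runif(1) < alpha) {
        x[j_sig] <- ls_prop
        lp <- loglik_eta(eta_of(x[seq_len(p)], omega, eps)) + log_prior_x(x)
      }
      if (it <= control$n_warmup)
        lstep_cs <- lstep_cs + (alpha - 0.44) / max(1, it)^0.6
    }
    if (nugget) {
      q_ep <- sum(eps^2)
      le_cur <- x[j_eps]
      le_prop <- le_cur + exp(lstep_ce) * stats::rnorm(1)
      tgt <- function(le) -n * le - q_ep / (2 * exp(2 * le)) -
        pc$lambda_eps * exp(le) + le
      alpha <- min(1, exp(tgt(le_prop) - tgt(le_cur)))
      if (stats::runif(1) < alpha) {
        x[j_eps] <- le_prop
        lp <- loglik_eta(eta_of(x[seq_len(p)], omega, eps)) + log_prior_x(x)
      }
      if (it <= control$n_warmup)
        lstep_ce <- lstep_ce + (alpha - 0.44) / max(1, it)^0.6
    }
    ## likelihood-preserving ridge move: shift intercept, counter-shift omega
    if (!is.na(j0)) {
      s <- exp(lstep_t) * stats::rnorm(1)
      nu_cur <- backsolve(R_corr, omega, transpose = TRUE) / exp(x[j_sig])
      w1 <- backsolve(R_corr, rep(1, n), transpose = TRUE)
      nu_prop <- nu_cur - (s / exp(x[j_sig])) * w1
      lr <- -0.5 * (sum(nu_prop^2) - sum(nu_cur^2)) +
        stats::dnorm(x[j0] + s, 0, b_sd, log = TRUE) -
        stats::dnorm(x[j0], 0, b_sd, log = TRUE)
      alpha_t <- min(1, exp(lr))
      if (stats::runif(1) < alpha_t) {
        omega <- omega - s
        x[j0] <- x[j0] + s
        b <- x[seq_len(p)]
      }
      if (it <= control$n_warmup)
        lstep_t <- lstep_t + (alpha_t - 0.44) / max(1, it)^0.6
    }
    if (it > control$n_warmup) {
      k <- it - control$n_warmup
      out$beta[k, ] <- x[seq_len(p)]
      out$omega[k, ] <- omega
      out$eta[k, ] <- eta_of(x[seq_len(p)], omega, eps)
      out$theta[k, ] <- x[(p + 1):d_x]
      out$hyper[k, ] <- x[(p + 1):d_x]
    }
  }
  out
}

#' Predict the coverage surface on a grid
#'
#' For each (thinned) posterior draw, the spatial effect at grid centroids
#' is drawn from the Gaussian-process conditional given the effect at the
#' data locations, using that draw's covariance parameters, and combined
#' with the regression part: \eqn{p_r(s) = \mathrm{expit}(x(s)'\beta_r +
#' \omega_r(s))}. The nugget represents between-cluster variation, not a
#' property of locations, and is not added to grid predictions: the
#' spatially structured surface is what is mapped and aggregated.
#'
#' @param fit A continuous-model `coverage_fit` from [fit_gp()].
#' @param grid Grid data.frame with `x_km`, `y_km`, covariate columns
#'   required by the fit's formula, and (optionally) `district_id` used to
#'   block the conditional simulation.
#' @param n_draws Number of posterior draws to propagate (thinned evenly;
#'   default 100).
#' @param seed Integer seed for the conditional simulation.
#' @return Object of class `coverage_surface`: list with `draws`
#'   (`n_draws x n_cells` matrix of coverage in (0,1)) and `grid`.
#' @export
predict_surface <- function(fit, grid, n_draws = 100, seed = 1) {
  stopifnot(inherits(fit, "coverage_fit"), fit$kind == "continuous")
  covs <- setdiff(colnames(fit$X), "(Intercept)")
  miss <- setdiff(covs, names(grid))
  if (length(miss))
    stop(sprintf("grid is missing covariate column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  Xg <- stats::model.matrix(fit$formula, grid)
  m_all <- nrow(fit$draws$eta)
  idx <- unique(round(seq(1, m_all, length.out = min(n_draws, m_all))))
  coords_d <- fit$coords
  coords_g <- as.matrix(grid[, c("x_km", "y_km")])
  Ddd <- as.matrix(stats::dist(coords_d))
  Ddg <- cross_dist(coords_d, coords_g)
  blocks <- if (!is.null(grid$district_id)) split(seq_len(nrow(grid)), grid$district_id)
            else list(seq_len(nrow(grid)))
  set.seed(substream_seed(seed, "predict-surface"))
  out <- matrix(NA_real_, length(idx), nrow(grid))
  for (r in seq_along(idx)) {
    k <- idx[r]
    sig <- fit$draws$sigma_omega[k]
    rng <- fit$draws$range_km[k]
    beta <- fit$draws$beta[k, ]
    z <- fit$draws$omega[k, ] / sig      # whitened field at data locations
    R <- chol_jitter(matern_correlation(Ddd, rng, sym = TRUE), 1)
    Ci_z <- backsolve(R, backsolve(R, z, transpose = TRUE))
    eta_fix <- drop(Xg %*% beta)
    for (b in blocks) {
      K <- matern_correlation(Ddg[, b, drop = FALSE], rng)
      mu <- drop(crossprod(K, Ci_z))
      V <- backsolve(R, K, transpose = TRUE)     # R^-T K
      Cb <- matern_correlation(as.matrix(stats::dist(coords_g[b, , drop = FALSE])), rng, sym = TRUE)
      cond <- Cb - crossprod(V)
      ## guard tiny negative diagonal from coincident points
      Rc <- tryCatch(chol(cond + diag(1e-10, length(b))), error = function(e) NULL)
      zb <- if (is.null(Rc)) {
        ev <- eigen(cond, symmetric = TRUE)
        ev$values[ev$values < 0] <- 0
        drop(ev$vectors %*% (sqrt(ev$values) * stats::rnorm(length(b))))
      } else drop(crossprod(Rc, stats::rnorm(length(b))))
      out[r, b] <- expit(eta_fix[b] + sig * (mu + zb))
    }
  }
  structure(list(draws = out, grid = grid, model_id = fit$model_id),
            class = "coverage_surface")
}

cross_dist <- function(a, b) {
  M <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  M[M < 0] <- 0
  sqrt(M)
}
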