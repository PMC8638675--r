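#' Prior specification for the discrete-area models
#'
#' Defaults follow common practice for survey small-area smoothing:
#' diffuse Gaussian priors on regression coefficients,
#' \eqn{\mathrm{logit}(\rho) \sim N(0, 0.45)} (variance) on the Leroux
#' autocorrelation, and a Gamma(0.1, 0.1) prior on the areal precision
#' \eqn{\sigma_\phi^{-2}}.
#'
#' @param beta_var Prior variance of each regression coefficient
#'   (default 1e6).
#' @param logit_rho_mean,logit_rho_var Gaussian prior on
#'   \eqn{\mathrm{logit}(\rho)}.
#' @param tau_shape,tau_rate Gamma prior on the precision
#'   \eqn{\tau_\phi = \sigma_\phi^{-2}}.
#' @return List of class `discrete_prior_spec`.
#' @export
discrete_prior_spec <- function(beta_var = 1e6, logit_rho_mean = 0,
                                logit_rho_var = 0.45,
                                tau_shape = 0.1, tau_rate = 0.1) {
  structure(list(beta_var = beta_var, logit_rho_mean = logit_rho_mean,
                 logit_rho_var = logit_rho_var,
                 tau_shape = tau_shape, tau_rate = tau_rate),
            class = "discrete_prior_spec")
}

## shared engine for the three discrete-area models.
## resp: list(y, n, v) with NA marking missing districts;
##   kind "binom" uses (y, n) with the (continuous) binomial log-likelihood,
##   kind "gauss" uses (y, v) with known heteroscedastic variances.
fit_discrete_engine <- function(model_id, kind, resp, X, W, prior, seed,
                                control) {
  n_A <- nrow(X); p <- ncol(X)
  W <- check_adjacency(W)
  if (nrow(W) != n_A) stop("adjacency dimension does not match data", call. = FALSE)
  obs <- if (kind == "binom") !is.na(resp$y) & !is.na(resp$n) & resp$n > 0
         else !is.na(resp$y) & !is.na(resp$v) & resp$v > 0
  if (!any(obs)) stop("all districts are missing; model unidentifiable", call. = FALSE)
  if (kind == "binom" && any(resp$y[obs] > resp$n[obs] + 1e-9))
    stop("vaccinated counts exceed sample sizes", call. = FALSE)

  ## standardize covariate columns; coefficients back-transformed on output
  sc <- standardize_X(X)
  Xs <- sc$X
  Lap <- diag(rowSums(W)) - W
  yo <- resp$y[obs]
  no <- if (kind == "binom") resp$n[obs] else NULL
  vo <- if (kind == "gauss") resp$v[obs] else NULL
  loglik_eta <- if (kind == "binom") {
    ## stable (continuous) binomial log-likelihood
    function(eta) sum(yo * eta - no * (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  } else {
    function(eta) -0.5 * sum((yo - eta)^2 / vo)
  }
  b_sd <- sqrt(prior$beta_var)

  j0 <- if (any(sc$const)) which(sc$const)[1] else NA_integer_
  chains <- lapply(seq_len(control$n_chains), function(ch) {
    set.seed(substream_seed(seed, paste0("discrete-", model_id, "-chain", ch)))
    run_discrete_chain(kind, loglik_eta, obs, Xs, Lap, prior, b_sd, control, j0)
  })

  beta_std <- combine_chains(chains, "beta")
  beta <- unstandardize_beta(beta_std, sc)
  colnames(beta) <- colnames(X)
  eta <- combine_chains(chains, "eta")
  diag_tab <- rhat_table(chains, c("beta", "hyper", "eta"))
  fit <- structure(list(
    model_id = model_id,
    draws = list(beta = beta,
                 phi = combine_chains(chains, "phi"),
                 rho = drop(combine_chains(chains, "rho")),
                 sigma2_phi = drop(combine_chains(chains, "sigma2")),
                 eta = eta, p = expit(eta)),
    diagnostics = diag_tab,
    converged = all(is.na(diag_tab$rhat) |
                      diag_tab$rhat < control$rhat_threshold),
    observed = obs, response = resp, X = X, W = W, prior = prior, seed = seed,
    control = control, kind = "discrete"
  ), class = "coverage_fit")
  fit
}

## Whitened (non-centered) parameterization: phi = tau^{-1/2} R_Q^{-1} u with
## u ~ N(0, I), which avoids the variance-random effect funnel; u moves by
## elliptical slice sampling, (beta, logit rho, log tau) by per-coordinate
## adaptive Metropolis whose likelihood sees phi(u, rho, tau).
run_discrete_chain <- function(kind, loglik_eta, obs, Xs, Lap, prior, b_sd,
                               control, j0 = NA_integer_) {
  n_A <- nrow(Xs); p <- ncol(Xs)
  n_tot <- control$n_warmup + control$n_iter
  u <- rep(0, n_A)
  lstep_t <- log(0.3)
  hy <- amh_vec_new(c(rep(0, p), 0, 0), step = 0.3)
  R_Q <- chol(0.5 * Lap + 0.5 * diag(n_A))
  phi_of <- function(u, R_Q, tau) backsolve(R_Q, u) / sqrt(tau)
  eta_of <- function(b, phi) drop(Xs %*% b) + phi
  hy_lp <- function(x) {
    b <- x[seq_len(p)]; rho <- stats::plogis(x[p + 1]); tau <- exp(x[p + 2])
    R <- chol(rho * Lap + (1 - rho) * diag(n_A))
    loglik_eta(eta_of(b, phi_of(u, R, tau))[obs]) +
      sum(stats::dnorm(b, 0, b_sd, log = TRUE)) +
      stats::dnorm(x[p + 1], prior$logit_rho_mean, sqrt(prior$logit_rho_var),
                   log = TRUE) +
      stats::dgamma(tau, prior$tau_shape, prior$tau_rate, log = TRUE) + x[p + 2]
  }
  keep <- control$n_iter
  out <- list(beta = matrix(NA_real_, keep, p),
              phi = matrix(NA_real_, keep, n_A),
              eta = matrix(NA_real_, keep, n_A),
              hyper = matrix(NA_real_, keep, 2),
              rho = matrix(NA_real_, keep, 1),
              sigma2 = matrix(NA_real_, keep, 1))
  for (it in seq_len(n_tot)) {
    b <- hy$x[seq_len(p)]
    rho <- stats::plogis(hy$x[p + 1]); tau <- exp(hy$x[p + 2])
    loglik_u <- function(uu) loglik_eta(eta_of(b, phi_of(uu, R_Q, tau))[obs])
    for (s in seq_len(control$n_ess)) {
      up <- ess_update(u, stats::rnorm(n_A), loglik_u)
      u <- up$f
    }
    hy$lp <- hy_lp(hy$x)
    hy <- amh_vec_step(hy, hy_lp, adapt = it <= control$n_warmup, iter = it)
    rho <- stats::plogis(hy$x[p + 1]); tau <- exp(hy$x[p + 2])
    R_Q <- chol(rho * Lap + (1 - rho) * diag(n_A))
    ## likelihood-preserving ridge move: shift intercept, counter-shift phi
    if (!is.na(j0)) {
      s <- exp(lstep_t) * stats::rnorm(1)
      u_prop <- u - s * sqrt(tau) * drop(R_Q %*% rep(1, n_A))
      b0 <- hy$x[j0]
      lr <- -0.5 * (sum(u_prop^2) - sum(u^2)) +
        stats::dnorm(b0 + s, 0, b_sd, log = TRUE) -
        stats::dnorm(b0, 0, b_sd, log = TRUE)
      alpha_t <- min(1, exp(lr))
      if (stats::runif(1) < alpha_t) {
        u <- u_prop; hy$x[j0] <- b0 + s; hy$lp <- NA_real_
      }
      if (it <= control$n_warmup)
        lstep_t <- lstep_t + (alpha_t - 0.44) / max(1, it)^0.6
    }
    if (it > control$n_warmup) {
      k <- it - control$n_warmup
      b <- hy$x[seq_len(p)]
      phi <- phi_of(u, R_Q, tau)
      out$beta[k, ] <- b
      out$phi[k, ] <- phi
      out$eta[k, ] <- eta_of(b, phi)
      out$hyper[k, ] <- hy$x[p + 1:2]
      out$rho[k, 1] <- rho
      out$sigma2[k, 1] <- 1 / tau
    }
  }
  out
}

standardize_X <- function(X) {
  m <- colMeans(X); s <- apply(X, 2, stats::sd)
  const <- s < 1e-12
  m[const] <- 0; s[const] <- 1
  Xs <- sweep(sweep(X, 2, m), 2, s, "/")
  list(X = Xs, m = m, s = s, const = const)
}

unstandardize_beta <- function(B, sc) {
  out <- sweep(B, 2, sc$s, "/")
  if (any(sc$const)) {
    j0 <- which(sc$const)[1]            # intercept column
    shift <- as.matrix(out[, !sc$const, drop = FALSE]) %*% sc$m[!sc$const]
    out[, j0] <- B[, j0] - drop(shift)
  }
  out
}

#' Fit the discrete-area coverage models
#'
#' Three Bayesian areal smoothing models sharing a Leroux CAR spatial
#' prior on district effects \eqn{\phi}:
#' \describe{
#'   \item{`fit_dunwb`}{unweighted binomial: \eqn{Y_{A_i} \sim
#'     \mathrm{Binomial}(N_{A_i}, p_{A_i})},
#'     \eqn{\mathrm{logit}\, p_{A_i} = x'_{A_i}\beta + \phi_{A_i}}.}
#'   \item{`fit_dln`}{logit-normal: the empirical logit \eqn{Y_L} of the
#'     direct estimate is Gaussian with known design-based variance
#'     \eqn{\hat\sigma^2_Y}; coverage is \eqn{\mathrm{expit}(\eta)}.}
#'   \item{`fit_dess`}{effective sample size: binomial with effective
#'     counts \eqn{Y_E \sim \mathrm{Binomial}(N_E, \tilde p)}; non-integer
#'     effective counts use the continuous binomial log-likelihood.}
#' }
#' Districts with missing responses (e.g. boundary direct estimates) are
#' excluded from the likelihood; their \eqn{\eta} and coverage draws are
#' generated per posterior draw from the linear predictor plus the CAR
#' conditional, i.e. their posterior predictive distribution.
#'
#' Inference is by MCMC: elliptical slice sampling of \eqn{(\beta, \phi)}
#' jointly, adaptive random-walk Metropolis on
#' \eqn{(\mathrm{logit}\,\rho, \log \tau_\phi)}. Covariates are
#' standardized internally and coefficients back-transformed; estimates of
#' coverage are invariant to this.
#'
#' @param district_data A data.frame with one row per district, sorted to
#'   match `graph`: counts `y_raw`/`n_raw` (D-UNWB), empirical logits
#'   `y_logit`/`var_logit` (D-LN) or effective counts `y_eff`/`n_eff`
#'   (D-ESS), e.g. from [direct_estimates()]. Covariate columns referenced
#'   by `formula` must be present.
#' @param graph Binary adjacency matrix of the districts.
#' @param formula RHS-only formula for the covariates (default `~ 1`).
#' @param prior A [discrete_prior_spec()].
#' @param seed Integer seed.
#' @param control An [mcmc_control()].
#' @return An object of class `coverage_fit` with posterior draw matrices
#'   (`beta`, `phi`, `rho`, `sigma2_phi`, `eta`, `p`), split-R-hat
#'   diagnostics, and a `converged` flag.
#' @seealso [fit_coverage()] for the unified interface,
#'   [fit_gp()] for the continuous models.
#' @export
fit_dunwb <- function(district_data, graph, formula = ~1,
                      prior = discrete_prior_spec(), seed = 1,
                      control = mcmc_control()) {
  X <- stats::model.matrix(formula, district_data)
  fit <- fit_discrete_engine("D-UNWB", "binom",
                             list(y = district_data$y_raw, n = district_data$n_raw),
                             X, graph, prior, seed, control)
  fit$district_id <- district_data$district_id
  fit
}

#' @rdname fit_dunwb
#' @export
fit_dln <- function(district_data, graph, formula = ~1,
                    prior = discrete_prior_spec(), seed = 1,
                    control = mcmc_control()) {
  X <- stats::model.matrix(formula, district_data)
  fit <- fit_discrete_engine("D-LN", "gauss",
                             list(y = district_data$y_logit, v = district_data$var_logit),
                             X, graph, prior, seed, control)
  fit$district_id <- district_data$district_id
  fit
}

#' @rdname fit_dunwb
#' @export
fit_dess <- function(district_data, graph, formula = ~1,
                     prior = discrete_prior_spec(), seed = 1,
                     control = mcmc_control()) {
  X <- stats::model.matrix(formula, district_data)
  fit <- fit_discrete_engine("D-ESS", "binom",
                             list(y = district_data$y_eff, n = district_data$n_eff),
                             X, graph, prior, seed, control)
  fit$district_id <- district_data$district_id
  fit
}
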