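## MCMC building blocks used by all five model fitters:
##  - elliptical slice sampling for blocks with (jointly) Gaussian priors,
##    which is rejection-free and requires no tuning or gradients;
##  - adaptive random-walk Metropolis for the low-dimensional hyperparameter
##    blocks, with Robbins-Monro step-size adaptation during warmup.

## One elliptical slice update of f (prior N(0, C)), given a prior draw nu
## and a log-likelihood function. Returns list(f, loglik).
ess_update <- function(f, nu, loglik_fn, ll_cur = NULL) {
  if (is.null(ll_cur)) ll_cur <- loglik_fn(f)
  logy <- ll_cur + log(stats::runif(1))
  theta <- stats::runif(1, 0, 2 * pi)
  lo <- theta - 2 * pi
  hi <- theta
  repeat {
    fp <- f * cos(theta) + nu * sin(theta)
    ll <- loglik_fn(fp)
    if (ll > logy) return(list(f = fp, loglik = ll))
    if (theta < 0) lo <- theta else hi <- theta
    theta <- stats::runif(1, lo, hi)
    if (hi - lo < 1e-10) return(list(f = f, loglik = ll_cur))
  }
}

## Adaptive random-walk Metropolis state for a d-dimensional block on an
## unconstrained scale. Target acceptance 0.3; adaptation only in warmup.
amh_new <- function(x, logpost, step = 0.3) {
  list(x = x, lp = logpost, lstep = log(step), acc = 0, n = 0)
}

amh_step <- function(st, logpost_fn, adapt, iter) {
  d <- length(st$x)
  prop <- st$x + exp(st$lstep) * stats::rnorm(d)
  lp_prop <- logpost_fn(prop)
  alpha <- min(1, exp(lp_prop - st$lp))
  if (is.finite(lp_prop) && stats::runif(1) < alpha) {
    st$x <- prop; st$lp <- lp_prop; st$acc <- st$acc + 1
  }
  st$n <- st$n + 1
  if (adapt) st$lstep <- st$lstep + (alpha - 0.3) / max(1, iter)^0.6
  st
}

## Per-coordinate adaptive random-walk Metropolis: each coordinate carries
## its own log step size, adapted toward 0.44 acceptance during warmup.
amh_vec_new <- function(x, step = 0.2) {
  list(x = x, lp = -Inf, lstep = rep(log(step), length(x)))
}

amh_vec_step <- function(st, logpost_fn, adapt, iter) {
  for (j in seq_along(st$x)) {
    prop <- st$x
    prop[j] <- prop[j] + exp(st$lstep[j]) * stats::rnorm(1)
    lp_prop <- logpost_fn(prop)
    alpha <- min(1, exp(lp_prop - st$lp))
    if (is.finite(lp_prop) && stats::runif(1) < alpha) {
      st$x <- prop; st$lp <- lp_prop
    }
    if (adapt)
      st$lstep[j] <- st$lstep[j] + (alpha - 0.44) / max(1, iter)^0.6
  }
  st
}

#' MCMC control settings
#'
#' @param n_chains Number of independent chains.
#' @param n_iter Kept iterations per chain (after warmup).
#' @param n_warmup Warmup (adaptation) iterations per chain, discarded.
#' @param n_ess Elliptical-slice sweeps of the Gaussian block per
#'   iteration.
#' @param rhat_threshold Split-R-hat above which the fit is flagged as not
#'   converged.
#' @return List of class `mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 4, n_iter = 1000, n_warmup = 1000,
                         n_ess = 5, rhat_threshold = 1.01) {
  structure(list(n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup,
                 n_ess = n_ess, rhat_threshold = rhat_threshold),
            class = "mcmc_control")
}

## stack per-chain draw matrices (iter x dim) into one matrix, and compute
## split-Rhat per scalar from the per-chain arrays
combine_chains <- function(chains, name) {
  do.call(rbind, lapply(chains, `[[`, name))
}

rhat_table <- function(chains, names) {
  out <- list()
  for (nm in names) {
    arrs <- lapply(chains, `[[`, nm)
    d <- ncol(arrs[[1]])
    for (j in seq_len(d)) {
      draws <- sapply(arrs, function(a) a[, j])
      lab <- if (d == 1) nm else sprintf("%s[%d]", nm, j)
      out[[lab]] <- split_rhat(draws)
    }
  }
  data.frame(parameter = names(out), rhat = unlist(out), row.names = NULL)
}
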