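## Independent oracles used by unit and acceptance tests. These are written
## from the standard textbook formulas, deliberately NOT sharing code with
## the package implementation they validate.

## Brute-force posterior mean of expit(eta_i) by grid quadrature.
## eta has prior N(0, Sigma(hyper)); the likelihood factorizes over
## districts. hyper_grid: data.frame of hyperparameter combinations with
## log-weights lw (prior mass at each combo, including any jacobians);
## Sigma_fn(row) returns the prior covariance of eta.
quad_posterior_mean <- function(loglik_fns, Sigma_fn, hyper_grid, lw,
                                eta_lim = c(-5, 5), n_eta = 41) {
  k <- length(loglik_fns)
  g <- seq(eta_lim[1], eta_lim[2], length.out = n_eta)
  idx <- as.matrix(expand.grid(rep(list(seq_len(n_eta)), k)))
  E <- matrix(g[idx], nrow(idx), k)
  ll <- rowSums(vapply(seq_len(k),
                       function(i) loglik_fns[[i]](E[, i]), numeric(nrow(E))))
  num <- rep(0, k); den <- 0
  for (r in seq_len(nrow(hyper_grid))) {
    S <- Sigma_fn(hyper_grid[r, , drop = FALSE])
    P <- solve(S)
    ld <- -0.5 * determinant(S, logarithm = TRUE)$modulus
    lq <- -0.5 * rowSums((E %*% P) * E)
    w <- exp(ll + lq + as.numeric(ld) + lw[r])
    den <- den + sum(w)
    num <- num + colSums(w * plogis(E))
  }
  num / den
}

## hyper grids with prior log-weights for the discrete models:
## logit(rho) ~ N(0, v_lrho) and tau = sigma_phi^-2 ~ Gamma(a, b),
## integrated on equally spaced grids of logit(rho) and log(tau)
discrete_hyper_grid <- function(n_rho = 13, n_tau = 17, v_lrho = 0.45,
                                a = 0.1, b = 0.1) {
  lr <- seq(-4, 4, length.out = n_rho) * sqrt(v_lrho)
  lt <- seq(-8, 6, length.out = n_tau)
  gr <- expand.grid(lrho = lr, ltau = lt)
  lw <- dnorm(gr$lrho, 0, sqrt(v_lrho), log = TRUE) +
    dgamma(exp(gr$ltau), a, b, log = TRUE) + gr$ltau
  list(grid = gr, lw = lw)
}

## prior covariance of eta = beta0 * 1 + phi for a Leroux CAR graph
leroux_eta_Sigma <- function(row, Lap, v_beta = 1e6) {
  n <- nrow(Lap)
  rho <- plogis(row$lrho); s2 <- 1 / exp(row$ltau)
  Q <- rho * Lap + (1 - rho) * diag(n)
  v_beta * matrix(1, n, n) + s2 * solve(Q)
}

## independent linearized design-variance of the HT ratio estimator:
## stratified, with-replacement between-PSU formula written long-hand
oracle_ht <- function(y_cl, n_cl, w_cl, stratum = NULL) {
  if (is.null(stratum)) stratum <- rep(1, length(y_cl))
  ## per-child weights are constant within cluster: totals use w * count
  Yhat <- sum(w_cl * y_cl)
  Nhat <- sum(w_cl * n_cl)
  p <- Yhat / Nhat
  v <- 0
  for (h in unique(stratum)) {
    i <- which(stratum == h)
    z <- w_cl[i] * y_cl[i] - p * w_cl[i] * n_cl[i]
    nh <- length(i)
    v <- v + nh / (nh - 1) * sum((z - mean(z))^2)
  }
  c(p = p, var = v / Nhat^2)
}

## Matern nu=1 correlation written independently from the Bessel formula
oracle_matern_corr <- function(d, r) {
  x <- sqrt(8) / r * d
  ifelse(d == 0, 1, x * besselK(x, 1))
}

## Exact posterior means of expit(eta) for a 2-cluster geostatistical toy
## by quadrature in rotated coordinates u = (eta1+eta2)/sqrt(2),
## v = (eta1-eta2)/sqrt(2): the exchangeable prior covariance (vague
## intercept + Matern + optional nugget) diagonalizes exactly there, and
## the v-grid scales with its own prior sd, which resolves the thin ridge
## that appears as the correlation approaches 1 in the long-range tail.
oracle_gp_2cluster <- function(y, N, d, pc, nugget = FALSE, v_beta = 1e6,
                               nl = 25, n_uv = 201) {
  ls_g <- seq(-5, 4, length.out = nl)
  lr_g <- seq(-2, 10, length.out = nl)
  le_g <- if (nugget) seq(-6, 2, length.out = 13) else 0
  num <- c(0, 0); den <- 0
  ug <- seq(-12, 12, length.out = n_uv); du <- ug[2] - ug[1]
  for (ls in ls_g) for (lr in lr_g) for (le in le_g) {
    s2 <- exp(2 * ls); r <- exp(lr)
    e2v <- if (nugget) exp(2 * le) else 0
    cr <- oracle_matern_corr(d, r)
    lam_u <- 2 * v_beta + s2 * (1 + cr) + e2v
    lam_v <- s2 * (1 - cr) + e2v
    lw <- pc_prior_logdensity(r, exp(ls), pc, if (nugget) exp(le)) +
      ls + lr + (if (nugget) le else 0)
    vmax <- max(min(10 * sqrt(lam_v), 16), 1e-6)
    vg <- seq(-vmax, vmax, length.out = n_uv); dv <- vg[2] - vg[1]
    e1 <- outer(ug, vg, function(u, v) (u + v) / sqrt(2))
    e2 <- outer(ug, vg, function(u, v) (u - v) / sqrt(2))
    ll <- y[1] * e1 - N[1] * (pmax(e1, 0) + log1p(exp(-abs(e1)))) +
      y[2] * e2 - N[2] * (pmax(e2, 0) + log1p(exp(-abs(e2))))
    lpu <- dnorm(ug, 0, sqrt(lam_u), log = TRUE)
    lpv <- dnorm(vg, 0, sqrt(lam_v), log = TRUE)
    w <- exp(sweep(sweep(ll, 1, lpu, "+"), 2, lpv, "+") + lw) * du * dv
    den <- den + sum(w)
    num <- num + c(sum(w * plogis(e1)), sum(w * plogis(e2)))
  }
  num / den
}

## closed-form CRPS of a Gaussian predictive at observation y
crps_gaussian <- function(y, mu, sigma) {
  z <- (y - mu) / sigma
  sigma * (z * (2 * pnorm(z) - 1) + 2 * dnorm(z) - 1 / sqrt(pi))
}

## ordinary-kriging weights by per-point solution of the dual system
oracle_krige <- function(coords, z, pred_xy, rng) {
  n <- nrow(coords)
  C <- exp(-as.matrix(dist(coords)) / rng)
  A <- cbind(rbind(C, 1), c(rep(1, n), 0))
  sapply(seq_len(nrow(pred_xy)), function(j) {
    d0 <- sqrt(colSums((t(coords) - pred_xy[j, ])^2))
    sol <- solve(A, c(exp(-d0 / rng), 1))
    sum(sol[1:n] * z)
  })
}

## small synthetic country fixture shared across tests
tiny_country <- function(seed = 7, n_districts = 6, n_clusters = 48,
                         extent = c(120, 120), res = 10, ...) {
  generate_country(country_config(
    n_districts = n_districts, extent_km = extent, grid_res_km = res,
    n_clusters_total = n_clusters, seed = seed, ...))
}

fast_ctrl <- function(n_chains = 2, n_iter = 400, n_warmup = 400)
  mcmc_control(n_chains = n_chains, n_iter = n_iter, n_warmup = n_warmup)
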