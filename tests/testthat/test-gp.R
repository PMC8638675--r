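sim_clusters <- function(seed, n = 40, extent = 200, sigma_omega = 0.6,
                         range_km = 80, beta0 = 0.8, sigma_eps = 0,
                         N_rng = c(15, 25)) {
  set.seed(seed)
  co <- cbind(runif(n, 0, extent), runif(n, 0, extent))
  om <- if (sigma_omega > 0) {
    S <- matern_covariance(co, sigma_omega^2, range_km)
    drop(t(chol(S + diag(1e-8, n))) %*% rnorm(n))
  } else rep(0, n)
  eta <- beta0 + om + rnorm(n, 0, sigma_eps)
  N <- sample(N_rng[1]:N_rng[2], n, replace = TRUE)
  data.frame(x_km = co[, 1], y_km = co[, 2], n_children = N,
             n_vaccinated = rbinom(n, N, plogis(eta)))
}

test_that("flat-surface data collapse the spatial variance toward zero", {
  cl <- sim_clusters(1, n = 30, sigma_omega = 0, beta0 = 0.8)
  f <- fit_gp(cl, ~1, model = "cgp", seed = 2,
              control = fast_ctrl(n_iter = 600, n_warmup = 600))
  b0 <- f$draws$beta[, 1]
  expect_true(quantile(b0, 0.05) < 0.8 && quantile(b0, 0.95) > 0.8)
  ## posterior mass of sigma_omega concentrates near 0 relative to its
  ## prior (PC exponential with P(sigma > 5) = 0.01, median ~ 3.77)
  prior_median <- log(2) / f$pc$lambda_sigma
  expect_lt(median(f$draws$sigma_omega), prior_median / 4)
})

test_that("surface prediction interpolates exactly at data locations", {
  cl <- sim_clusters(3, n = 25)
  f <- fit_gp(cl, ~1, model = "cgp", seed = 4, control = fast_ctrl())
  g <- data.frame(x_km = cl$x_km[1:10], y_km = cl$y_km[1:10])
  surf <- predict_surface(f, g, n_draws = 30, seed = 5)
  idx <- unique(round(seq(1, nrow(f$draws$p), length.out = 30)))
  expect_equal(surf$draws, f$draws$p[idx, 1:10], tolerance = 1e-5)
})

test_that("far-field prediction reverts to the marginal process", {
  cl <- sim_clusters(6, n = 30, extent = 100, range_km = 50)
  f <- fit_gp(cl, ~1, model = "cgp", seed = 7,
              control = fast_ctrl(n_iter = 800, n_warmup = 800))
  ## a point ~ 10 ranges away from every cluster
  g <- data.frame(x_km = 5000, y_km = 5000)
  surf <- predict_surface(f, g, n_draws = 800, seed = 8)
  om_star <- logit(surf$draws[, 1]) -
    f$draws$beta[unique(round(seq(1, nrow(f$draws$p), length.out = 800))), 1]
  expect_equal(mean(om_star), 0, tolerance = 0.15)
  expect_equal(var(om_star), mean(f$draws$sigma_omega^2), tolerance = 0.5)
})

test_that("fits and predictions are equivariant to coordinate translation", {
  cl <- sim_clusters(9, n = 20)
  f1 <- fit_gp(cl, ~1, model = "cgp", seed = 10, control = fast_ctrl(n_iter = 200, n_warmup = 200))
  cl2 <- cl
  cl2$x_km <- cl2$x_km + 1000; cl2$y_km <- cl2$y_km - 250
  f2 <- fit_gp(cl2, ~1, model = "cgp", seed = 10, control = fast_ctrl(n_iter = 200, n_warmup = 200))
  expect_identical(f1$draws$eta, f2$draws$eta)
  g1 <- data.frame(x_km = c(50, 80), y_km = c(50, 10))
  g2 <- data.frame(x_km = g1$x_km + 1000, y_km = g1$y_km - 250)
  s1 <- predict_surface(f1, g1, n_draws = 20, seed = 11)
  s2 <- predict_surface(f2, g2, n_draws = 20, seed = 11)
  ## cross-distances are computed via the expanded quadratic form, so
  ## translation equivariance holds to floating-point rounding only
  expect_equal(s1$draws, s2$draws, tolerance = 1e-6)
})

test_that("the nugget model nests the pure-GP model as sigma_eps -> 0", {
  cl <- sim_clusters(12, n = 35)
  ## a PC prior essentially pinning sigma_eps at 0 makes C-GPIID reproduce
  ## C-GP on the same data and seed within Monte-Carlo error
  pc0 <- pc_prior_spec(r0 = 0.05 * diff(range(cl$y_km)), sigma_eps0 = 1e-8)
  ctrl <- fast_ctrl(n_iter = 700, n_warmup = 700)
  f_iid <- fit_gp(cl, ~1, model = "cgpiid", pc = pc0, seed = 13, control = ctrl)
  f_gp <- fit_gp(cl, ~1, model = "cgp", seed = 13, control = ctrl)
  expect_lt(max(f_iid$draws$sigma_eps), 1e-6)
  expect_equal(colMeans(f_iid$draws$p), colMeans(f_gp$draws$p),
               tolerance = 0.03)
})

test_that("grid covariates are checked before prediction", {
  cl <- sim_clusters(14, n = 20)
  cl$z <- rnorm(20)
  f <- fit_gp(cl, ~z, model = "cgp", seed = 15, control = fast_ctrl(n_iter = 150, n_warmup = 150))
  g <- data.frame(x_km = 1:3, y_km = 1:3)
  expect_error(predict_surface(f, g), "z")
})
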