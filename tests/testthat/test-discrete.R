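path3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)

toy_direct <- function() {
  d <- data.frame(district_id = 1:3,
                  n_raw = c(40, 50, 30), y_raw = c(22, 35, 12))
  d$p_hat_dir <- d$y_raw / d$n_raw
  d$var_p_dir <- c(0.004, 0.003, 0.006)
  d <- empirical_logit(d)
  d <- effective_sample_size(d)
  d$boundary_flag <- FALSE
  d
}

test_that("posterior draws respect their supports and sample sizes", {
  d <- toy_direct()
  f <- fit_dunwb(d, path3, ~1, seed = 2, control = fast_ctrl())
  expect_true(all(f$draws$p > 0 & f$draws$p < 1))
  expect_true(all(f$draws$rho > 0 & f$draws$rho < 1))
  expect_true(all(f$draws$sigma2_phi > 0))
  expect_equal(nrow(f$draws$p), 2 * 400)
  expect_equal(ncol(f$draws$p), 3)
  expect_s3_class(f, "coverage_fit")
})

test_that("district relabelling permutes the posterior accordingly", {
  d <- toy_direct()
  perm <- c(3, 1, 2)
  dp <- d[perm, ]; dp$district_id <- 1:3
  Wp <- path3[perm, perm]
  f1 <- fit_dunwb(d, path3, ~1, seed = 7, control = fast_ctrl())
  f2 <- fit_dunwb(dp, Wp, ~1, seed = 7, control = fast_ctrl())
  expect_equal(colMeans(f2$draws$p), colMeans(f1$draws$p)[perm],
               tolerance = 0.04)
})

test_that("weaker data increase posterior uncertainty (monotone information)", {
  d <- toy_direct()
  ctrl <- fast_ctrl(n_iter = 600, n_warmup = 600)
  ## D-LN: inflating one district's known variance inflates its posterior sd
  f1 <- fit_dln(d, path3, ~1, seed = 3, control = ctrl)
  d2 <- d; d2$var_logit[2] <- d2$var_logit[2] * 25
  f2 <- fit_dln(d2, path3, ~1, seed = 3, control = ctrl)
  expect_gt(sd(f2$draws$p[, 2]), sd(f1$draws$p[, 2]))
  ## D-ESS: shrinking one district's effective sample size does the same
  f3 <- fit_dess(d, path3, ~1, seed = 3, control = ctrl)
  d3 <- d
  d3$n_eff[2] <- d3$n_eff[2] / 25
  d3$y_eff[2] <- d3$n_eff[2] * d3$p_hat_dir[2]
  f4 <- fit_dess(d3, path3, ~1, seed = 3, control = ctrl)
  expect_gt(sd(f4$draws$p[, 2]), sd(f3$draws$p[, 2]))
})

test_that("known-variance Gaussian limit pins the linear predictor", {
  d <- toy_direct()
  d$var_logit <- rep(1e-8, 3)
  f <- fit_dln(d, path3, ~1, seed = 4, control = fast_ctrl())
  expect_equal(colMeans(f$draws$eta), d$y_logit, tolerance = 0.005)
  expect_true(all(apply(f$draws$eta, 2, sd) < 0.01))
})

test_that("with rho near 0 and a diffuse areal prior, districts decouple", {
  ## prior spec forcing rho ~ 0 and a very large sigma2_phi: the posterior
  ## for district 1 should be driven by district-1 data alone
  pr <- discrete_prior_spec(logit_rho_mean = -30, logit_rho_var = 1e-6,
                            tau_shape = 0.05, tau_rate = 5)
  d <- toy_direct()
  ctrl <- fast_ctrl(n_iter = 800, n_warmup = 800)
  f1 <- fit_dunwb(d, path3, ~1, prior = pr, seed = 6, control = ctrl)
  d2 <- d
  d2$y_raw[3] <- 5            # perturb a different district's data
  f2 <- fit_dunwb(d2, path3, ~1, prior = pr, seed = 6, control = ctrl)
  expect_equal(mean(f1$draws$p[, 1]), mean(f2$draws$p[, 1]), tolerance = 0.03)
  expect_gt(abs(mean(f1$draws$p[, 3]) - mean(f2$draws$p[, 3])), 0.1)
})

test_that("D-ESS on raw counts is indistinguishable from D-UNWB", {
  ## under SRS the effective counts equal the raw counts
  d <- toy_direct()
  d$n_eff <- d$n_raw; d$y_eff <- d$y_raw
  ctrl <- fast_ctrl(n_iter = 800, n_warmup = 800)
  f_ess <- fit_dess(d, path3, ~1, seed = 8, control = ctrl)
  f_bin <- fit_dunwb(d, path3, ~1, seed = 8, control = ctrl)
  expect_equal(colMeans(f_ess$draws$p), colMeans(f_bin$draws$p),
               tolerance = 0.02)
  expect_equal(apply(f_ess$draws$p, 2, sd), apply(f_bin$draws$p, 2, sd),
               tolerance = 0.02)
})

test_that("missing districts receive finite, wider posterior predictives", {
  d <- toy_direct()
  d$y_logit[1] <- NA; d$var_logit[1] <- NA; d$boundary_flag[1] <- TRUE
  f <- fit_dln(d, path3, ~1, seed = 9, control = fast_ctrl())
  expect_true(all(is.finite(f$draws$p[, 1])))
  ## the imputed district is at least as uncertain as its observed neighbors
  sds <- apply(f$draws$p, 2, sd)
  expect_gte(sds[1], max(sds[2:3]) * 0.99)
  ## all-missing data are rejected
  d_all <- d
  d_all$y_logit <- NA; d_all$var_logit <- NA
  expect_error(fit_dln(d_all, path3, ~1, control = fast_ctrl()),
               "unidentifiable")
})

test_that("covariate standardization leaves coverage estimates invariant", {
  d <- toy_direct()
  d$z <- c(10, 30, 20)
  f1 <- fit_dunwb(d, path3, ~z, seed = 11, control = fast_ctrl(n_iter = 600, n_warmup = 600))
  d2 <- d; d2$z <- d$z / 1000      # wildly different covariate scale
  f2 <- fit_dunwb(d2, path3, ~z, seed = 11, control = fast_ctrl(n_iter = 600, n_warmup = 600))
  expect_equal(colMeans(f1$draws$p), colMeans(f2$draws$p), tolerance = 0.03)
  ## back-transformed slope scales accordingly
  expect_equal(mean(f1$draws$beta[, "z"]) * 1000, mean(f2$draws$beta[, "z"]),
               tolerance = 0.35 * abs(mean(f2$draws$beta[, "z"])) + 0.02)
})

test_that("response validation catches impossible counts", {
  d <- toy_direct()
  d$y_raw[1] <- d$n_raw[1] + 5
  expect_error(fit_dunwb(d, path3, ~1, control = fast_ctrl()), "exceed")
})
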