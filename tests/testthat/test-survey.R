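make_clusters <- function(y, n, w, district = 1, stratum = "all") {
  data.frame(cluster_id = seq_along(y), x_km = seq_along(y), y_km = 0,
             district_id = district,
             stratum = stratum,
             n_children = n, n_vaccinated = y, weight = w)
}

test_that("weight normalization sums to district sample size and preserves ratios", {
  ## two clusters (N=10, w=2) and (N=10, w=4): normalized per-child weights
  ## 2/3 and 4/3, summing over children to N_A = 20
  cl <- make_clusters(y = c(5, 6), n = c(10, 10), w = c(2, 4))
  out <- normalize_weights(cl)
  expect_equal(out$w_norm, c(2 * 20 / 60, 4 * 20 / 60))
  expect_equal(sum(out$w_norm * out$n_children), 20)
  ## equal weights normalize to 1 per child
  cl2 <- make_clusters(y = c(1, 2, 3), n = c(5, 5, 5), w = c(7, 7, 7))
  expect_equal(normalize_weights(cl2)$w_norm, rep(1, 3))
  ## scale invariance
  cl3 <- cl; cl3$weight <- cl3$weight * 13
  expect_equal(normalize_weights(cl3)$w_norm, out$w_norm)
})

test_that("direct estimator reduces to the raw proportion under equal weights", {
  cl <- make_clusters(y = c(3, 7, 5), n = c(10, 10, 10), w = c(1, 1, 1))
  d <- direct_estimates(cl)
  expect_equal(d$p_hat_dir, 15 / 30)
  expect_equal(d$n_raw, 30)
  expect_equal(d$y_raw, 15)
})

test_that("identical cluster proportions give zero design variance", {
  cl <- make_clusters(y = c(4, 8), n = c(10, 20), w = c(2, 5))
  d <- direct_estimates(cl)
  expect_equal(d$var_p_dir, 0)
  expect_true(is.na(d$n_eff))   # undefined ESS flagged missing
})

test_that("linearized variance matches the independent long-hand oracle", {
  y <- c(2, 4, 6); n <- c(10, 10, 10); w <- c(1, 1, 2)
  cl <- normalize_weights(make_clusters(y, n, w))
  est <- direct_estimate(cl)
  orc <- oracle_ht(y, n, cl$w_norm)
  expect_equal(unname(est["p_hat_dir"]), unname(orc["p"]), tolerance = 1e-12)
  expect_equal(unname(est["var_p_dir"]), unname(orc["var"]), tolerance = 1e-12)
  ## stratified case against the same oracle
  strat <- c("u", "u", "r", "r", "r")
  y2 <- c(3, 5, 2, 7, 4); n2 <- rep(10, 5); w2 <- c(1, 2, 1, 1, 3)
  cl2 <- normalize_weights(make_clusters(y2, n2, w2, stratum = strat))
  est2 <- direct_estimate(cl2)
  orc2 <- oracle_ht(y2, n2, cl2$w_norm, strat)
  expect_equal(unname(est2["var_p_dir"]), unname(orc2["var"]), tolerance = 1e-12)
})

test_that("direct estimate is invariant to uniform weight rescaling", {
  y <- c(2, 9, 6); n <- c(10, 12, 9); w <- c(1, 3, 2)
  d1 <- direct_estimates(make_clusters(y, n, w))
  d2 <- direct_estimates(make_clusters(y, n, w * 100))
  expect_equal(d1$p_hat_dir, d2$p_hat_dir)
  expect_equal(d1$var_p_dir, d2$var_p_dir)
})

test_that("empirical logit and its variance follow the delta rule", {
  d <- data.frame(p_hat_dir = 0.5, var_p_dir = 0.01)
  e <- empirical_logit(d)
  expect_equal(e$y_logit, 0)
  expect_equal(e$var_logit, 0.01 / 0.25^2)   # = 0.16
  ## inverse-logit identity
  d2 <- data.frame(p_hat_dir = exp(1) / (1 + exp(1)), var_p_dir = 0.01)
  expect_equal(empirical_logit(d2)$y_logit, 1)
  ## non-boundary districts round-trip to machine precision
  d3 <- data.frame(p_hat_dir = c(0.123, 0.87), var_p_dir = c(0.01, 0.02))
  expect_equal(expit(empirical_logit(d3)$y_logit), d3$p_hat_dir)
})

test_that("boundary estimates are flagged and propagate as missing", {
  cl <- rbind(make_clusters(c(10, 10), c(10, 10), c(1, 2), district = 1),
              make_clusters(c(3, 4), c(10, 10), c(1, 1), district = 2))
  d <- direct_estimates(cl)
  expect_true(d$boundary_flag[d$district_id == 1])
  expect_true(is.na(d$y_logit[d$district_id == 1]))
  expect_true(is.na(d$var_logit[d$district_id == 1]))
  expect_true(is.na(d$n_eff[d$district_id == 1]))
  expect_false(d$boundary_flag[d$district_id == 2])
})

test_that("effective sample size identities hold", {
  d <- data.frame(p_hat_dir = 0.5, var_p_dir = 0.0025)
  e <- effective_sample_size(d)
  expect_equal(e$n_eff, 100)
  expect_equal(e$y_eff, 50)
})

test_that("SRS gives ESS near N and full clustering collapses ESS to cluster count", {
  ## every child its own PSU: var equals the SRS variance up to n/(n-1)
  set.seed(42)
  n <- 400
  y <- rbinom(n, 1, 0.6)
  cl <- make_clusters(y, rep(1, n), rep(1, n))
  d <- direct_estimates(cl)
  expect_lt(abs(d$n_eff - n) / n, 0.05)
  ## identical outcomes within large clusters (ICC ~ 1): ESS ~ #clusters
  k <- 30; m <- 25
  yc <- rbinom(k, 1, 0.5)
  cl2 <- make_clusters(yc * m, rep(m, k), rep(1, k))
  d2 <- direct_estimates(cl2)
  expect_lt(abs(d2$n_eff - k) / k, 0.2)
  expect_lt(d2$n_eff, d2$n_raw)  # design effect > 1 shrinks information
})

test_that("districts with no children are dropped with a warning", {
  cl <- rbind(make_clusters(c(3, 5), c(10, 10), c(1, 1), district = 1),
              make_clusters(0, 0, 1, district = 2))
  expect_warning(out <- normalize_weights(cl), "zero surveyed children")
  expect_false(2 %in% out$district_id)
})
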