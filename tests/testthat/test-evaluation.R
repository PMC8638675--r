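test_that("point metrics follow their definitions", {
  expect_equal(metric_rbias(c(0.5, 0.5), c(0.5, 0.5)), 0)
  expect_equal(metric_rbias(c(0.55, 0.45), c(0.5, 0.5)), 0)
  expect_equal(metric_rbias(0.6, 0.5), 0.2)
  expect_equal(unname(metric_rmse_mae(c(0.5, 0.5), c(0.4, 0.6))),
               c(0.1, 0.1))
  expect_equal(unname(metric_rmse_mae(0.8, 0.5)), c(0.3, 0.3))
  expect_equal(unname(metric_rmse_mae(c(1, 2), c(1, 2))), c(0, 0))
  expect_error(metric_rbias(0.5, 0), "positive")
})

test_that("CRPS estimator matches hand and closed-form oracles", {
  ## degenerate draws: CRPS = |c - p| exactly
  expect_equal(metric_crps(rep(0.7, 50), 0.2), 0.5)
  ## two draws {0, 1} with p = 0.5: 0.5 - 1/4 = 0.25 by the double sum
  expect_equal(metric_crps(c(0, 1), 0.5, method = "double"), 0.25)
  expect_equal(metric_crps(c(0, 1), 0.5), 0.25)
  ## sorted O(m log m) form equals the explicit double sum
  set.seed(10)
  for (m in c(11, 200, 1000)) {
    x <- rnorm(m)
    expect_equal(metric_crps(x, 0.3), metric_crps(x, 0.3, method = "double"),
                 tolerance = 1e-12)
  }
  ## Gaussian draws against the closed-form Gaussian CRPS
  x <- rnorm(1e5, 0.6, 0.15)
  expect_equal(metric_crps(x, 0.5), crps_gaussian(0.5, 0.6, 0.15),
               tolerance = 0.01)
  ## permutation invariance
  y <- rnorm(500)
  expect_equal(metric_crps(y, 0), metric_crps(sample(y), 0))
})

test_that("leave-one-district-out splits are clean partitions", {
  co <- tiny_country(seed = 31)
  cl <- co$clusters
  d <- direct_estimates(normalize_weights(cl))
  ids <- d$district_id
  ## discrete: held-out responses masked, covariates and others untouched
  sp <- lodo_split(d, ids[2], "discrete")
  expect_true(all(is.na(sp[sp$district_id == ids[2],
                           c("y_raw", "y_logit", "n_eff")])))
  expect_identical(as.data.frame(sp)[sp$district_id != ids[2], ],
                   as.data.frame(d)[d$district_id != ids[2], ])
  ## continuous: clusters of the held-out district dropped, others unchanged
  spc <- lodo_split(cl, ids[2], "continuous")
  expect_false(ids[2] %in% spc$district_id)
  expect_identical(spc, cl[cl$district_id != ids[2], ])
  tab_before <- table(cl$district_id[cl$district_id != ids[2]])
  expect_equal(table(spc$district_id), tab_before)
  ## the union of held-out cluster sets over all districts is the full data
  held <- do.call(rbind, lapply(ids, function(i) cl[cl$district_id == i, ]))
  expect_equal(nrow(held), nrow(cl))
  expect_setequal(held$cluster_id, cl$cluster_id)
})

test_that("metrics on a hand-worked fixture match spreadsheet arithmetic", {
  p <- c(0.5, 0.8, 0.4)
  draws <- list(c(0.4, 0.6), c(0.7, 0.9), c(0.1, 0.5))
  p_hat <- vapply(draws, mean, numeric(1))     # 0.5, 0.8, 0.3
  expect_equal(metric_rbias(p_hat, p), (0 + 0 + (-0.1 / 0.4)) / 3)
  rm2 <- metric_rmse_mae(p_hat, p)
  expect_equal(unname(rm2["rmse"]), sqrt(0.01 / 3))
  expect_equal(unname(rm2["mae"]), 0.1 / 3)
  ## CRPS by hand: district 1 draws {0.4, 0.6}, p = 0.5:
  ## E|X-p| = 0.1; E|X-X*|/2 = (0+0.2+0.2+0)/8 = 0.05 -> 0.05
  expect_equal(metric_crps(draws[[1]], p[1]), 0.05)
  crps_all <- mean(mapply(metric_crps, draws, p))
  expect_equal(crps_all, mean(c(0.05,
                                mean(abs(c(0.7, 0.9) - 0.8)) - 0.05,
                                mean(abs(c(0.1, 0.5) - 0.4)) - 0.1)))
})

test_that("a predictor equal to the reference scores zero", {
  p <- c(0.3, 0.6, 0.9)
  expect_equal(metric_rbias(p, p), 0)
  expect_equal(unname(metric_rmse_mae(p, p)), c(0, 0))
})

test_that("D-LN held-out predictions ignore the held-out response", {
  co <- tiny_country(seed = 33)
  d <- direct_estimates(normalize_weights(co$clusters))
  i <- d$district_id[1]
  sp <- lodo_split(d, i, "discrete")
  f1 <- fit_dln(sp, co$W, ~1, seed = 5, control = fast_ctrl())
  ## perturb the held-out district's (already masked) source columns
  d2 <- d
  d2$y_logit[1] <- d2$y_logit[1] + 5
  sp2 <- lodo_split(d2, i, "discrete")
  f2 <- fit_dln(sp2, co$W, ~1, seed = 5, control = fast_ctrl())
  expect_equal(f1$draws$p[, 1], f2$draws$p[, 1])
})
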