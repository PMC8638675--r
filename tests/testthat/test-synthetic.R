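test_that("generated country satisfies its structural invariants", {
  co <- tiny_country(seed = 11, n_districts = 4, n_clusters = 40)
  cfg <- co$config

  expect_equal(nrow(co$clusters), 40)
  expect_true(all(table(co$clusters$district_id) >= 2))
  ## grid cells partition the rectangle into districts
  expect_true(all(co$grid$district_id %in% co$districts$district_id))
  ## population shares sum to one within each district
  qs <- tapply(co$grid$q, co$grid$district_id, sum)
  expect_true(all(abs(qs - 1) < 1e-12))
  ## both strata exist everywhere
  st <- table(co$grid$district_id, co$grid$stratum)
  expect_true(all(st > 0))
  ## every emitted cluster surveys at least 2 children
  expect_true(all(co$clusters$n_children >= 2))
  ## clusters sit on grid centroids inside their own district
  idx <- mapply(function(x, y) which(co$grid$x_km == x & co$grid$y_km == y),
                co$clusters$x_km, co$clusters$y_km)
  expect_equal(co$grid$district_id[idx], co$clusters$district_id)
  ## adjacency is symmetric binary with empty diagonal
  expect_equal(co$W, t(co$W))
  expect_true(all(diag(co$W) == 0))
})

test_that("generation is deterministic given the seed", {
  a <- tiny_country(seed = 5)
  b <- tiny_country(seed = 5)
  expect_identical(a$clusters, b$clusters)
  expect_identical(a$truth, b$truth)
  expect_identical(a$W, b$W)
  c2 <- tiny_country(seed = 6)
  expect_false(identical(a$clusters, c2$clusters))
})

test_that("normalization holds on a larger irregular country", {
  co <- generate_country(country_config(
    n_districts = 30, extent_km = c(600, 900), grid_res_km = 30,
    n_clusters_total = 120, gp_params = list(sigma_omega = 0, range_km = 100),
    seed = 2))
  qs <- tapply(co$grid$q, co$grid$district_id, sum)
  expect_true(all(abs(qs - 1) <= 1e-12))
})

test_that("config validation rejects impossible requests", {
  expect_error(country_config(n_districts = 1), "n_districts")
  expect_error(country_config(urban_fraction = 1.2), "urban_fraction")
  expect_error(country_config(n_clusters_total = 10000, extent_km = c(100, 100),
                              grid_res_km = 10), "grid cells")
})

test_that("degenerate GP gives the pure regression surface", {
  cfg <- country_config(n_districts = 4, extent_km = c(100, 100),
                        grid_res_km = 10, n_clusters_total = 20,
                        gp_params = list(sigma_omega = 0, range_km = 100),
                        seed = 4)
  co <- generate_country(cfg)
  X <- cbind(1, co$grid$remoteness)
  expect_equal(co$truth$p_true, expit(drop(X %*% cfg$beta)), tolerance = 1e-12)
})

test_that("latent field matches its marginal variance and local correlation", {
  ## ensemble variance per cell over replicate draws approaches sigma^2
  grid <- expand.grid(x_km = seq(5, 95, by = 10), y_km = seq(5, 95, by = 10))
  grid$cell_id <- seq_len(nrow(grid))
  reps <- 200
  om <- sapply(seq_len(reps), function(r)
    simulate_latent_surface(grid, list(sigma_omega = 0.5, range_km = 200),
                            beta = 0, seed = 1000 + r, covariates = NULL)$omega)
  v <- mean(apply(om, 1, var))
  expect_lt(abs(v - 0.25), 0.25 * 0.15)
  ## two cells 1 km apart under a 500 km range are almost perfectly correlated
  g2 <- data.frame(x_km = c(0, 1), y_km = c(0, 0), cell_id = 1:2)
  om2 <- sapply(seq_len(500), function(r)
    simulate_latent_surface(g2, list(sigma_omega = 0.5, range_km = 500),
                            beta = 0, seed = 2000 + r, covariates = NULL)$omega)
  expect_gt(cor(om2[1, ], om2[2, ]), 0.99)
})

test_that("empirical variogram of the latent field rises with distance", {
  grid <- expand.grid(x_km = seq(10, 190, by = 20), y_km = seq(10, 190, by = 20))
  grid$cell_id <- seq_len(nrow(grid))
  rng <- 150
  om <- sapply(seq_len(100), function(r)
    simulate_latent_surface(grid, list(sigma_omega = 0.7, range_km = rng),
                            beta = 0, seed = 3000 + r, covariates = NULL)$omega)
  D <- as.matrix(dist(grid[, c("x_km", "y_km")]))
  iu <- which(upper.tri(D) & D <= rng, arr.ind = TRUE)
  d <- D[iu]
  gamma <- rowMeans(sapply(seq_len(ncol(om)), function(r)
    0.5 * (om[iu[, 1], r] - om[iu[, 2], r])^2))
  bins <- cut(d, breaks = seq(0, rng, length.out = 7))
  gbar <- tapply(gamma, bins, mean)
  ## monotone non-decreasing binned variogram (small Monte-Carlo allowance)
  expect_true(all(diff(gbar) > -0.01 * 0.7^2))
})

test_that("survey outcomes are unbiased when the surface is flat", {
  ## sigma_eps = 0 and constant p = 0.5: mean of Y/N over many clusters
  ## stays within 3 binomial standard errors of 0.5
  cfg <- country_config(n_districts = 6, extent_km = c(400, 400),
                        grid_res_km = 10, n_clusters_total = 1000,
                        children_per_cluster = c(20, 20),
                        gp_params = list(sigma_omega = 0, range_km = 100),
                        beta = c(0, 0), nugget_sd = 0, seed = 9)
  co <- generate_country(cfg)
  expect_true(all(abs(co$truth$p_true - 0.5) < 1e-12))
  pbar <- mean(co$clusters$n_vaccinated / co$clusters$n_children)
  expect_true(pbar > 0.48 && pbar < 0.52)
})

test_that("equal inclusion probabilities give equal weights", {
  co <- tiny_country(seed = 21)
  ## force a uniform-population country: all cells equal pop -> within each
  ## stratum inclusion probabilities equal -> equal weights within stratum
  co$grid$pop <- rep(1, nrow(co$grid))
  co$grid$q <- stats::ave(co$grid$q, co$grid$district_id,
                          FUN = function(z) rep(1 / length(z), length(z)))
  cl <- simulate_survey(co, co$config)
  w_by <- tapply(cl$weight, interaction(cl$district_id, cl$stratum, drop = TRUE),
                 function(w) diff(range(w)))
  expect_true(all(w_by < 1e-12))
})

test_that("a stratum with no population raises a degenerate-design error", {
  co <- tiny_country(seed = 22)
  co$grid$pop[co$grid$district_id == 1 & co$grid$stratum == "urban"] <- 0
  expect_error(simulate_survey(co, co$config), "degenerate")
})

test_that("district-level true coverage is a proper population-weighted mean", {
  co <- tiny_country(seed = 13)
  p <- co$districts$p_true_district
  expect_true(all(p > 0 & p < 1))
  d1 <- co$grid$district_id == co$districts$district_id[1]
  expect_equal(p[1], sum(co$truth$p_true[d1] * co$grid$q[d1]), tolerance = 1e-12)
})
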