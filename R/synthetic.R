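#' Configuration for a synthetic survey country
#'
#' Defines the study conditions for the synthetic-data generator: a
#' rectangular country partitioned into irregular districts (Voronoi cells
#' of random seed points), a regular grid carrying population and
#' covariates, a smooth latent logit-coverage surface with a Matern (nu=1)
#' Gaussian-process component, and a stratified (urban/rural) two-stage
#' cluster survey with unequal inclusion probabilities, emulating the
#' structure of DHS vaccination-coverage data.
#'
#' @param n_districts Number of districts (>= 2).
#' @param extent_km Width/height of the country rectangle in km.
#' @param grid_res_km Grid cell size in km (default 5, the resolution at
#'   which national coverage surfaces are conventionally produced).
#' @param n_clusters_total Total number of survey clusters.
#' @param children_per_cluster Integer range (min, max) of children aged
#'   12-23 months surveyed per cluster.
#' @param urban_fraction Fraction of clusters allocated to the urban
#'   stratum (urban areas are oversampled relative to their population).
#' @param urban_quantile Within-district population quantile above which a
#'   grid cell is classed urban (default 0.2, i.e. top 20% of cells).
#' @param gp_params List with `sigma_omega` (logit-scale marginal sd) and
#'   `range_km` (Matern practical range).
#' @param beta Coefficient vector (intercept first) for the latent surface;
#'   length must be `1 + length(covariates)`.
#' @param covariates Names of grid covariates entering the latent surface.
#' @param nugget_sd Between-cluster (nugget) sd \eqn{\sigma_\epsilon \ge 0}
#'   applied on the logit scale at cluster level only.
#' @param seed Master integer seed; all stages draw through named
#'   substreams of it.
#' @return A list of class `country_config`.
#' @export
country_config <- function(n_districts = 25,
                           extent_km = c(300, 300),
                           grid_res_km = 5,
                           n_clusters_total = 300,
                           children_per_cluster = c(10, 30),
                           urban_fraction = 0.4,
                           urban_quantile = 0.2,
                           gp_params = list(sigma_omega = 0.6, range_km = 75),
                           beta = c(1.0, -0.5),
                           covariates = "remoteness",
                           nugget_sd = 0.3,
                           seed = 1L) {
  cfg <- list(n_districts = as.integer(n_districts),
              extent_km = as.numeric(extent_km),
              grid_res_km = grid_res_km,
              n_clusters_total = as.integer(n_clusters_total),
              children_per_cluster = as.integer(children_per_cluster),
              urban_fraction = urban_fraction,
              urban_quantile = urban_quantile,
              gp_params = gp_params,
              beta = as.numeric(beta),
              covariates = covariates,
              nugget_sd = nugget_sd,
              seed = as.integer(seed))
  if (cfg$n_districts < 2) stop("n_districts must be >= 2", call. = FALSE)
  if (cfg$grid_res_km <= 0) stop("grid_res_km must be > 0", call. = FALSE)
  if (length(cfg$extent_km) != 2 || any(cfg$extent_km <= 0))
    stop("extent_km must be a positive (width, height) pair", call. = FALSE)
  if (cfg$urban_fraction <= 0 || cfg$urban_fraction >= 1)
    stop("urban_fraction must be in (0, 1)", call. = FALSE)
  if (cfg$gp_params$sigma_omega < 0 || cfg$gp_params$range_km <= 0)
    stop("gp_params: sigma_omega >= 0 and range_km > 0 required", call. = FALSE)
  if (cfg$nugget_sd < 0) stop("nugget_sd must be >= 0", call. = FALSE)
  if (length(cfg$beta) != 1 + length(cfg$covariates))
    stop("beta must have length 1 + length(covariates)", call. = FALSE)
  if (length(cfg$children_per_cluster) != 2 ||
      cfg$children_per_cluster[2] < 2)
    stop("children_per_cluster must be a (min, max) range reaching at least 2",
         call. = FALSE)
  n_cells <- prod(floor(cfg$extent_km / cfg$grid_res_km))
  if (cfg$n_clusters_total > n_cells)
    stop(sprintf("invalid config: %d clusters requested but only %d grid cells",
                 cfg$n_clusters_total, n_cells), call. = FALSE)
  class(cfg) <- "country_config"
  cfg
}

#' Generate a synthetic country with survey data
#'
#' Deterministic given `config$seed`. Districts are Voronoi cells of
#' random seed points (two Lloyd relaxation steps regularize extreme
#' cells), clipped to the rectangle; adjacency is defined by shared borders
#' of positive length. Grid cells are assigned to the district containing
#' their centroid; the population raster is a log-Gaussian field
#' normalized within each district to shares `q`; an urban stratum (top
#' population quantile within district) and a rural stratum exist in every
#' district. The latent coverage surface and the cluster survey are then
#' simulated (see [simulate_latent_surface()] and [simulate_survey()]).
#'
#' @param config A [country_config()].
#' @return A list of class `synthetic_country` with elements `districts`
#'   (data.frame incl. polygon list-column), `W` (binary adjacency),
#'   `grid` (cell centroids with `district_id`, `pop`, `q`, `stratum` and
#'   covariates), `truth` (per-cell `omega`, `eta`, `p_true` and
#'   per-district population-weighted true coverage `p_true_district`),
#'   `clusters` (the cluster table) and `config`.
#' @export
generate_country <- function(config) {
  stopifnot(inherits(config, "country_config"))
  w <- config$extent_km[1]; h <- config$extent_km[2]
  res <- config$grid_res_km
  gx <- seq(res / 2, w - res / 2 + 1e-9, by = res)
  gy <- seq(res / 2, h - res / 2 + 1e-9, by = res)
  grid <- expand.grid(x_km = gx, y_km = gy)
  grid$cell_id <- seq_len(nrow(grid))

  tess <- with_substream(config$seed, "districts",
                         make_districts(config, grid))
  grid$district_id <- tess$assignment

  grid <- with_substream(config$seed, "population",
                         add_population(grid, config))
  grid <- with_substream(config$seed, "covariates",
                         add_covariates(grid, config))

  truth <- simulate_latent_surface(
    grid, config$gp_params, config$beta, seed = config$seed,
    covariates = config$covariates)
  p_dist <- tapply(truth$p_true * grid$q, grid$district_id, sum)
  districts <- tess$districts
  districts$p_true_district <- as.numeric(p_dist[as.character(districts$district_id)])

  country <- structure(list(districts = districts, W = tess$W, grid = grid,
                            truth = truth, clusters = NULL, config = config),
                       class = "synthetic_country")
  country$clusters <- simulate_survey(country, config)
  country
}

## Voronoi districts via deldir, with Lloyd relaxation and a minimum-cell
## guard so every district can host clusters in both strata
make_districts <- function(config, grid) {
  n <- config$n_districts
  w <- config$extent_km[1]; h <- config$extent_km[2]
  rw <- c(0, w, 0, h)
  min_cells <- max(4, 2 * ceiling(config$n_clusters_total / nrow(grid)))
  for (attempt in 1:50) {
    sx <- stats::runif(n, 0, w); sy <- stats::runif(n, 0, h)
    for (it in 1:2) {   # Lloyd steps: move seeds to cell centroids
      a <- nearest_seed(grid$x_km, grid$y_km, sx, sy)
      for (i in seq_len(n)) {
        idx <- a == i
        if (any(idx)) { sx[i] <- mean(grid$x_km[idx]); sy[i] <- mean(grid$y_km[idx]) }
      }
    }
    a <- nearest_seed(grid$x_km, grid$y_km, sx, sy)
    if (all(tabulate(a, n) >= min_cells)) break
    if (attempt == 50)
      stop("could not place districts so that each has enough grid cells; coarsen the grid or reduce n_districts", call. = FALSE)
  }
  dd <- deldir::deldir(sx, sy, rw = rw)
  tiles <- deldir::tile.list(dd)
  polys <- lapply(tiles, function(t) cbind(x = t$x, y = t$y))
  ## adjacency: Voronoi segments of positive length between pairs
  seg <- dd$dirsgs
  len <- sqrt((seg$x1 - seg$x2)^2 + (seg$y1 - seg$y2)^2)
  W <- matrix(0L, n, n)
  keep <- len > 1e-9
  for (k in which(keep)) {
    i <- seg$ind1[k]; j <- seg$ind2[k]
    W[i, j] <- W[j, i] <- 1L
  }
  districts <- data.frame(district_id = seq_len(n), seed_x = sx, seed_y = sy)
  districts$polygon <- polys
  list(districts = districts, W = W, assignment = a)
}

## nearest seed index per point; ties resolved to the smaller district id
nearest_seed <- function(px, py, sx, sy) {
  D2 <- outer(px, sx, function(a, b) (a - b)^2) +
    outer(py, sy, function(a, b) (a - b)^2)
  max.col(-D2, ties.method = "first")
}

## population: log-Gaussian field, normalized to within-district shares q;
## urban stratum = top population quantile within each district
add_population <- function(grid, config) {
  coords <- as.matrix(grid[, c("x_km", "y_km")])
  pop_range <- 0.25 * min(config$extent_km)
  S <- matern_covariance(coords, sigma2_omega = 1, range_km = pop_range)
  u <- drop(t(chol_jitter(S, 1)) %*% stats::rnorm(nrow(grid)))
  grid$pop <- exp(3 + 1.2 * u)
  pops <- tapply(grid$pop, grid$district_id, sum)
  grid$q <- grid$pop / as.numeric(pops[as.character(grid$district_id)])
  grid$stratum <- "rural"
  for (d in unique(grid$district_id)) {
    idx <- grid$district_id == d
    thr <- stats::quantile(grid$pop[idx], 1 - config$urban_quantile, type = 1)
    urb <- idx & grid$pop >= thr
    if (!any(urb)) urb <- idx & grid$pop == max(grid$pop[idx])
    grid$stratum[urb] <- "urban"
    if (all(grid$stratum[idx] == "urban")) # degenerate tiny district
      grid$stratum[which(idx)[which.min(grid$pop[idx])]] <- "rural"
  }
  grid
}

## grid covariates; "remoteness" = standardized distance to a random city
add_covariates <- function(grid, config) {
  if ("remoteness" %in% config$covariates) {
    cx <- stats::runif(1, 0.25, 0.75) * max(grid$x_km)
    cy <- stats::runif(1, 0.25, 0.75) * max(grid$y_km)
    d <- sqrt((grid$x_km - cx)^2 + (grid$y_km - cy)^2)
    grid$remoteness <- as.numeric(scale(d))
  }
  extra <- setdiff(config$covariates, "remoteness")
  for (nm in extra) { # additional smooth synthetic covariates if requested
    gx <- stats::runif(2, -1, 1)
    v <- gx[1] * grid$x_km / max(grid$x_km) + gx[2] * grid$y_km / max(grid$y_km)
    grid[[nm]] <- as.numeric(scale(v + stats::rnorm(nrow(grid), 0, 0.1)))
  }
  grid
}

#' Simulate the latent logit-coverage surface
#'
#' Draws the spatial random effect \eqn{\omega} from a zero-mean Gaussian
#' process with Matern (nu = 1) covariance over the grid centroids (exact
#' dense Cholesky) and forms the true coverage surface
#' \eqn{p(s) = \mathrm{expit}(x(s)'\beta + \omega(s))}. The nugget is a
#' cluster-level phenomenon and is not applied to the grid truth.
#'
#' @param grid Grid data.frame with `x_km`, `y_km` and covariate columns.
#' @param gp_params List with `sigma_omega` and `range_km`.
#' @param beta Coefficients, intercept first.
#' @param seed Master seed (substream "latent").
#' @param covariates Covariate column names (default: those implied by
#'   `length(beta) - 1` taken from `attr` or `"remoteness"`).
#' @return data.frame with `cell_id`, `omega`, `eta`, `p_true`.
#' @export
simulate_latent_surface <- function(grid, gp_params, beta, seed,
                                    covariates = "remoteness") {
  if (gp_params$range_km <= 0) stop("range_km must be > 0", call. = FALSE)
  if (gp_params$sigma_omega < 0) stop("sigma_omega must be >= 0", call. = FALSE)
  covariates <- covariates[seq_len(length(beta) - 1)]
  X <- cbind(1, as.matrix(grid[, covariates, drop = FALSE]))
  n <- nrow(grid)
  if (gp_params$sigma_omega == 0) {
    omega <- rep(0, n)
  } else {
    coords <- as.matrix(grid[, c("x_km", "y_km")])
    S <- matern_covariance(coords, gp_params$sigma_omega^2, gp_params$range_km)
    omega <- with_substream(seed, "latent",
                            drop(t(chol_jitter(S, gp_params$sigma_omega^2)) %*%
                                   stats::rnorm(n)))
  }
  eta <- drop(X %*% beta) + omega
  data.frame(cell_id = grid$cell_id %||% seq_len(n), omega = omega,
             eta = eta, p_true = expit(eta))
}

#' Simulate the stratified two-stage cluster survey
#'
#' Allocates clusters to districts proportionally to population (minimum
#' two per district), splits them between urban and rural strata with
#' urban oversampling, samples cluster cells within strata with
#' probability proportional to cell population (without replacement), and
#' sets the sampling weight to the inverse of the (approximate) inclusion
#' probability. Cluster outcomes are
#' \eqn{Y_i \sim \mathrm{Binomial}(N_i, \mathrm{expit}(\mathrm{logit}\,
#' p(s_i) + \epsilon_i))} with iid nugget \eqn{\epsilon_i \sim
#' N(0, \sigma^2_\epsilon)}. Cluster sizes with \eqn{N \le 1} are redrawn
#' (such clusters are excluded from real surveys).
#'
#' @param country A `synthetic_country` (grid + truth present).
#' @param config The [country_config()].
#' @return Cluster table data.frame: `cluster_id`, `x_km`, `y_km`,
#'   `district_id`, `stratum`, `n_children`, `n_vaccinated`, `weight`.
#' @export
simulate_survey <- function(country, config) {
  grid <- country$grid; truth <- country$truth
  if (is.null(truth)) stop("latent surface missing; run generate_country()", call. = FALSE)
  with_substream(config$seed, "survey", {
    ids <- sort(unique(grid$district_id))
    pops <- as.numeric(tapply(grid$pop, grid$district_id, sum)[as.character(ids)])
    alloc <- allocate_proportional(config$n_clusters_total, pops, min_each = 2)
    rows <- list()
    for (k in seq_along(ids)) {
      d <- ids[k]
      gd <- grid[grid$district_id == d, , drop = FALSE]
      n_d <- alloc[k]
      n_urb <- min(max(1, round(config$urban_fraction * n_d)), n_d - 1)
      take <- c(urban = n_urb, rural = n_d - n_urb)
      for (h in c("urban", "rural")) {
        gh <- gd[gd$stratum == h, , drop = FALSE]
        n_h <- take[[h]]
        if (nrow(gh) == 0 || sum(gh$pop) <= 0)
          stop(sprintf("degenerate design: district %s stratum %s has no population", d, h),
               call. = FALSE)
        if (n_h > nrow(gh)) { # shift surplus to the other stratum
          surplus <- n_h - nrow(gh)
          n_h <- nrow(gh)
          other <- setdiff(c("urban", "rural"), h)
          take[[other]] <- take[[other]] + surplus
        }
        if (n_h == 0) next
        pick <- sample(nrow(gh), n_h, prob = gh$pop)
        incl <- pmin(n_h * gh$pop[pick] / sum(gh$pop), 0.9999)
        for (j in seq_along(pick)) {
          cell <- gh[pick[j], ]
          nvals <- config$children_per_cluster[1]:config$children_per_cluster[2]
          repeat {
            N <- nvals[sample.int(length(nvals), 1)]
            if (N >= 2) break
          }
          eta_c <- truth$eta[truth$cell_id == cell$cell_id] +
            stats::rnorm(1, 0, config$nugget_sd)
          Y <- stats::rbinom(1, N, expit(eta_c))
          rows[[length(rows) + 1]] <- data.frame(
            x_km = cell$x_km, y_km = cell$y_km, district_id = d,
            stratum = h, n_children = N, n_vaccinated = Y,
            weight = 1 / incl[j])
        }
      }
    }
    out <- do.call(rbind, rows)
    out <- cbind(cluster_id = seq_len(nrow(out)), out)
    rownames(out) <- NULL
    out
  })
}

## largest-remainder proportional allocation with a minimum per unit
allocate_proportional <- function(total, sizes, min_each = 2) {
  k <- length(sizes)
  if (total < k * min_each)
    stop(sprintf("cannot allocate %d clusters with a minimum of %d to %d districts",
                 total, min_each, k), call. = FALSE)
  base <- rep(min_each, k)
  rem <- total - sum(base)
  share <- rem * sizes / sum(sizes)
  extra <- floor(share)
  left <- rem - sum(extra)
  if (left > 0) {
    ord <- order(share - extra, decreasing = TRUE)
    extra[ord[seq_len(left)]] <- extra[ord[seq_len(left)]] + 1
  }
  base + extra
}

#' @export
print.synthetic_country <- function(x, ...) {
  cat("Synthetic survey country\n")
  cat(sprintf("  %d districts, %.0f x %.0f km, %d grid cells (%.0f km res)\n",
              nrow(x$districts), x$config$extent_km[1], x$config$extent_km[2],
              nrow(x$grid), x$config$grid_res_km))
  cat(sprintf("  %d clusters, %d children\n", nrow(x$clusters),
              sum(x$clusters$n_children)))
  cat(sprintf("  true national coverage (pop-weighted): %.3f\n",
              sum(x$truth$p_true * x$grid$pop) / sum(x$grid$pop)))
  invisible(x)
}
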