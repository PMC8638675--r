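#' Read and validate a cluster table
#'
#' Reads a cluster-level CSV (columns `cluster_id`, `x_km`, `y_km`,
#' `district_id`, `stratum`, `n_children`, `n_vaccinated`, `weight`),
#' validates the schema, and applies the standard exclusion rule: clusters
#' where at most one child was surveyed are dropped with a warning (their
#' count is reported).
#'
#' @param path CSV file path.
#' @return Validated cluster table `data.frame`.
#' @export
read_cluster_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("cluster_id", "x_km", "y_km", "district_id", "stratum",
           "n_children", "n_vaccinated", "weight")
  stopifnot_named(df, req, sprintf("cluster table '%s'", path))
  if (any(df$n_vaccinated > df$n_children))
    stop("n_vaccinated exceeds n_children in cluster table", call. = FALSE)
  if (any(df$weight <= 0)) stop("weights must be positive", call. = FALSE)
  small <- df$n_children <= 1
  if (any(small)) {
    warning(sprintf("excluding %d cluster(s) where <= 1 child was surveyed",
                    sum(small)))
    df <- df[!small, , drop = FALSE]
  }
  df
}

#' @rdname read_cluster_table
#' @param clusters Cluster table to write.
#' @export
write_cluster_table <- function(clusters, path) {
  utils::write.csv(clusters, path, row.names = FALSE)
  invisible(path)
}

#' District polygons with embedded adjacency as GeoJSON
#'
#' Districts are written as a GeoJSON FeatureCollection of polygons with
#' properties `district_id` and `neighbors` (the adjacency list), in
#' planar km coordinates. `read_districts()` round-trips the polygons and
#' rebuilds the binary adjacency matrix from the stored neighbor lists.
#' `adjacency_from_polygons()` recomputes adjacency geometrically: two
#' districts are neighbors when their polygons share a border of positive
#' length (at least two common vertices).
#'
#' @param districts District data.frame with `district_id` and a `polygon`
#'   list-column of two-column coordinate matrices.
#' @param W Binary adjacency matrix.
#' @param path File path.
#' @return `read_districts()`: list with `districts` and `W`.
#' @export
write_districts <- function(districts, W, path) {
  feats <- lapply(seq_len(nrow(districts)), function(i) {
    poly <- districts$polygon[[i]]
    ring <- rbind(poly, poly[1, , drop = FALSE])   # close the ring
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(k) unname(ring[k, ])))),
         properties = list(district_id = districts$district_id[i],
                           neighbors = which(W[i, ] > 0)))
  })
  gj <- list(type = "FeatureCollection",
             crs = list(type = "name", properties = list(name = "planar-km")),
             features = feats)
  writeLines(jsonlite::toJSON(gj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname write_districts
#' @export
read_districts <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- gj$features
  n <- length(feats)
  ids <- vapply(feats, function(f) f$properties$district_id, numeric(1))
  polys <- lapply(feats, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    ring[-nrow(ring), , drop = FALSE]              # drop closing vertex
  })
  W <- matrix(0L, n, n)
  for (i in seq_len(n)) {
    nb <- unlist(feats[[i]]$properties$neighbors)
    W[i, nb] <- 1L
  }
  W <- 1L * ((W + t(W)) > 0)
  districts <- data.frame(district_id = ids)
  districts$polygon <- polys
  list(districts = districts, W = W)
}

#' @rdname write_districts
#' @param polygons List of polygon coordinate matrices.
#' @param tol Vertex matching tolerance (km).
#' @export
adjacency_from_polygons <- function(polygons, tol = 1e-6) {
  n <- length(polygons)
  keys <- lapply(polygons, function(p)
    paste(round(p[, 1] / tol) * tol, round(p[, 2] / tol) * tol))
  W <- matrix(0L, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sum(keys[[i]] %in% keys[[j]]) >= 2) W[i, j] <- W[j, i] <- 1L
  }
  W
}

#' Grid, estimate and surface serialization
#'
#' The grid (cell centroids with population shares and covariates) and
#' posterior surfaces are stored as plain CSV so every artifact of a study
#' run is text. `write_surface()` stores the grid coordinates together
#' with per-cell posterior mean/sd and, optionally, the draws.
#'
#' @param grid Grid data.frame.
#' @param path File path.
#' @export
write_grid <- function(grid, path) {
  utils::write.csv(grid, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_grid <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname write_grid
#' @param est District estimates data.frame (from [district_estimates()]).
#' @export
write_estimates <- function(est, path) {
  utils::write.csv(est, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_grid
#' @param surface A `coverage_surface`.
#' @param draws Whether to include the full draw matrix columns.
#' @export
write_surface <- function(surface, path, draws = FALSE) {
  out <- data.frame(x_km = surface$grid$x_km, y_km = surface$grid$y_km,
                    district_id = surface$grid$district_id %||% NA,
                    mean = colMeans(surface$draws),
                    sd = apply(surface$draws, 2, stats::sd))
  if (draws) out <- cbind(out, t(surface$draws))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_grid
#' @export
read_surface <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Run the full synthetic coverage study
#'
#' End-to-end pipeline: generate a synthetic country, compute direct
#' estimates, fit the requested models on the full data, produce district
#' estimate tables with exceedance probabilities, optionally run the
#' leave-one-district-out comparison, and write every artifact (CSV /
#' GeoJSON / JSON manifest) to `out_dir`. Re-running with the same
#' configuration and seeds reproduces the artifacts byte for byte.
#'
#' @param config A [country_config()], or path to a YAML file with fields
#'   understood by [country_config()] plus optional `models`,
#'   `covariates`, `thresholds`, `cv`.
#' @param out_dir Output directory (created if needed).
#' @param models Models to fit.
#' @param covariates `"with"` and/or `"without"`.
#' @param thresholds Exceedance thresholds.
#' @param cv Run the leave-one-district-out comparison.
#' @param seed Seed for model fitting (the country uses `config$seed`).
#' @param control_discrete,control_gp [mcmc_control()] for the full-data
#'   fits.
#' @return Invisibly, a list with the country, fits, estimate tables, the
#'   comparison (if run) and artifact paths.
#' @export
run_study <- function(config, out_dir,
                      models = c("dunwb", "dln", "dess", "cgpiid", "cgp"),
                      covariates = "with",
                      thresholds = c(0.80, 0.95),
                      cv = TRUE, seed = 1,
                      control_discrete = mcmc_control(n_chains = 2, n_iter = 800,
                                                      n_warmup = 800),
                      control_gp = mcmc_control(n_chains = 1, n_iter = 800,
                                                n_warmup = 800)) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "country_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)

  message("generating synthetic country ...")
  country <- generate_country(config)
  write_cluster_table(country$clusters, path("clusters.csv"))
  write_districts(country$districts, country$W, path("districts.geojson"))
  write_grid(country$grid, path("grid.csv"))
  utils::write.csv(country$truth, path("truth.csv"), row.names = FALSE)

  clusters <- normalize_weights(country$clusters)
  direct <- direct_estimates(clusters)
  grid <- country$grid
  for (nm in config$covariates) {
    direct[[nm]] <- as.numeric(district_covariate(grid[[nm]], grid))
    clusters[[nm]] <- grid_lookup(grid, clusters$x_km, clusters$y_km, nm)
  }
  write_estimates(direct, path("direct_estimates.csv"))

  form <- if ("with" %in% covariates && length(config$covariates))
    stats::as.formula(paste("~", paste(config$covariates, collapse = "+"))) else ~1
  fits <- list(); est_tabs <- list()
  for (mod in models) {
    message("fitting ", model_label(mod), " ...")
    if (mod %in% c("dunwb", "dln", "dess")) {
      fit <- switch(mod,
        dunwb = fit_dunwb(direct, country$W, form, seed = substream_seed(seed, mod),
                          control = control_discrete),
        dln = fit_dln(direct, country$W, form, seed = substream_seed(seed, mod),
                      control = control_discrete),
        dess = fit_dess(direct, country$W, form, seed = substream_seed(seed, mod),
                        control = control_discrete))
      dd <- fit$draws$p
      colnames(dd) <- as.character(direct$district_id)
    } else {
      fit <- fit_gp(clusters, form, model = mod, seed = substream_seed(seed, mod),
                    control = control_gp)
      surf <- predict_surface(fit, grid, n_draws = 100,
                              seed = substream_seed(seed, paste0(mod, "-pred")))
      write_surface(surf, path(sprintf("surface_%s.csv", mod)))
      dd <- aggregate_surface(surf, grid)
    }
    est <- district_estimates(dd, thresholds)
    write_estimates(est, path(sprintf("estimates_%s.csv", mod)))
    fits[[mod]] <- fit; est_tabs[[mod]] <- est
  }

  comparison <- NULL
  if (cv) {
    message("running leave-one-district-out comparison ...")
    comparison <- run_comparison(country, models = models,
                                 covariates = covariates, seed = seed)
    write_estimates(comparison$table, path("comparison.csv"))
  }

  artifacts <- list.files(out_dir, full.names = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("vaxsae")),
    config = unclass(config), fit_seed = seed, models = models,
    covariates = covariates, thresholds = thresholds,
    files = lapply(stats::setNames(artifacts, basename(artifacts)),
                   function(f) unname(tools::md5sum(f))))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA, pretty = TRUE),
             path("manifest.json"))

  invisible(list(country = country, direct = direct, fits = fits,
                 estimates = est_tabs, comparison = comparison,
                 out_dir = out_dir))
}

#' @rdname run_study
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- intersect(names(y), names(formals(country_config)))
  cfg <- do.call(country_config, y[known])
  cfg
}
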