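#' @title Synthetic world generation
#' @description Generators for a fully synthetic study region — monthly
#'   climate with smooth gradients and correlated noise, soils, Gaussian
#'   species niches with known truth, spatially biased occurrence sampling,
#'   pseudo-RCM anomaly ensembles, land-use fractions and species traits —
#'   so every downstream stage can be validated against ground truth.
#' @name synthetic-world
NULL

# separable Gaussian smoothing with edge renormalisation; gives the
# correlated (rather than white) noise fields real climatologies show
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  smooth_1d <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1, i - half); hi <- min(n, i + half)
      kk <- k[(lo - i + half + 1):(hi - i + half + 1)]
      out[i] <- sum(v[lo:hi] * kk) / sum(kk)
    }
    out
  }
  m <- apply(m, 2, smooth_1d)
  t(apply(m, 1, smooth_1d))
}

#' Generate a synthetic baseline world
#'
#' Builds a 26-layer stack: 12 monthly temperatures (`t_01`..`t_12`, deg C)
#' with a north-south gradient (colder at the top of the grid), a seasonal
#' cycle peaking in July, and smooth correlated noise; 12 monthly
#' precipitations (`p_01`..`p_12`, mm/month, non-negative) with a west-east
#' gradient and winter-peaking seasonality; soil `pH` (3.5-8.5) and soil
#' organic carbon `occ` (g/kg). Deterministic per seed.
#'
#' @param n_cols,n_rows Grid dimensions (>= 20 each).
#' @param cell_size_m Cell size in metres (default 10000, a ~10 km cell).
#' @param seed Integer seed.
#' @param t_gradient_degC Total north-south mean-temperature span (default 15).
#' @param seasonal_amp_degC Seasonal half-amplitude (default 9).
#' @param noise_sd_degC Spatially correlated temperature noise sd (default 0.6).
#' @return A `tr_stack` with 26 layers.
#' @export
make_world <- function(n_cols, n_rows, cell_size_m = 10000, seed = 1,
                       t_gradient_degC = 15, seasonal_amp_degC = 9,
                       noise_sd_degC = 0.6) {
  stopifnot(n_cols >= 20, n_rows >= 20)
  set.seed(seed)
  g <- grid_spec(0, n_rows * cell_size_m, cell_size_m, -cell_size_m,
                 n_cols, n_rows, crs_tag = "EPSG:3035")
  lat <- matrix(seq(0, 1, length.out = n_rows), n_rows, n_cols)        # 0=N
  lon <- matrix(seq(0, 1, length.out = n_cols), n_rows, n_cols, byrow = TRUE)

  relief <- gaussian_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows),
                            sigma = max(2, n_rows / 12))
  relief <- relief / stats::sd(relief)
  t_noise <- relief * noise_sd_degC
  # annual-mean T: warm south (high row index), cool north, relief imprint
  t_mean <- 3 + t_gradient_degC * lat + t_noise
  # continentality grows eastward: larger seasonal amplitude inland
  amp <- seasonal_amp_degC * (0.7 + 0.6 * lon)

  p_noise <- gaussian_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows),
                             sigma = max(2, n_rows / 12))
  p_noise <- p_noise / stats::sd(p_noise)
  p_mean <- 55 + 45 * (1 - lon) + 10 * p_noise       # wetter west
  p_season <- 0.45 * (0.4 + 0.6 * lon)               # stronger seasonality east

  # independent smooth weather noise per month keeps the derived seasonal
  # aggregates (annual total, summer/winter means, seasonality) from being
  # exact linear combinations of each other, as in real climatologies
  month_field <- function() {
    f <- gaussian_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows),
                         sigma = max(2, n_rows / 15))
    f / stats::sd(f)
  }
  layers <- list()
  for (m in 1:12) {
    phase <- cos(2 * pi * (m - 7) / 12)              # +1 in July
    layers[[sprintf("t_%02d", m)]] <-
      make_raster(g, t_mean + amp * phase + 0.8 * month_field())
    pm <- p_mean * (1 + p_season * cos(2 * pi * (m - 1) / 12)) *
      (1 + 0.25 * month_field())                     # winter peak
    layers[[sprintf("p_%02d", m)]] <- make_raster(g, pmax(pm, 0))
  }
  ph_field <- gaussian_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows),
                              sigma = max(2, n_rows / 10))
  ph_field <- ph_field / stats::sd(ph_field)
  layers[["pH"]] <- make_raster(g, pmin(pmax(6 + 1.1 * ph_field - 0.8 * lat,
                                             3.5), 8.5))
  oc_field <- gaussian_smooth(matrix(stats::rnorm(n_rows * n_cols), n_rows),
                              sigma = max(2, n_rows / 10))
  oc_field <- oc_field / stats::sd(oc_field)
  layers[["occ"]] <- make_raster(g, pmax(25 + 30 * (1 - lat) + 12 * oc_field,
                                         1))
  raster_stack(layers)
}

#' Generate a pseudo-RCM anomaly ensemble
#'
#' Coarsens the world by block means to make each model's control
#' climatology, then perturbs it: temperature gets an additive warming field
#' (per-model mean drawn around `warming_mean_degC`, plus a smooth spatial
#' pattern), precipitation is scaled by a per-model factor field around
#' `precip_factor_mean`. With all noise sds zero, future equals control
#' shifted exactly by the stated means.
#'
#' @param world Baseline `tr_stack` from [make_world()].
#' @param n_models Number of ensemble members (>= 1).
#' @param warming_mean_degC Ensemble-mean warming (default 3).
#' @param precip_factor_mean Ensemble-mean precipitation factor (default 0.9).
#' @param coarsen_factor Integer block size (>= 2).
#' @param seed Integer seed.
#' @param model_sd_degC Between-model spread of mean warming (default 0.5).
#' @param spatial_sd_degC Within-model spatial warming pattern sd (default 0.4).
#' @param factor_sd Between-model spread of the precipitation factor
#'   (default 0.05).
#' @return List of `n_models` elements, each `list(control =, future =)`
#'   monthly `tr_stack`s on the coarse grid.
#' @export
make_future <- function(world, n_models = 11, warming_mean_degC = 3,
                        precip_factor_mean = 0.9, coarsen_factor = 4,
                        seed = 1, model_sd_degC = 0.5, spatial_sd_degC = 0.4,
                        factor_sd = 0.05) {
  stopifnot(n_models >= 1, coarsen_factor >= 2)
  set.seed(seed)
  month_names <- c(sprintf("t_%02d", 1:12), sprintf("p_%02d", 1:12))
  control_layers <- lapply(month_names, function(nm)
    block_mean(world$layers[[nm]], coarsen_factor))
  names(control_layers) <- month_names
  control <- raster_stack(control_layers)
  cg <- control$grid

  out <- vector("list", n_models)
  for (k in seq_len(n_models)) {
    dT_mean <- warming_mean_degC +
      if (model_sd_degC > 0) stats::rnorm(1, 0, model_sd_degC) else 0
    pf_mean <- precip_factor_mean +
      if (factor_sd > 0) stats::rnorm(1, 0, factor_sd) else 0
    if (spatial_sd_degC > 0) {
      pat <- gaussian_smooth(matrix(stats::rnorm(cg$n_rows * cg$n_cols),
                                    cg$n_rows), sigma = max(1, cg$n_rows / 8))
      pat <- (pat - mean(pat)) / stats::sd(pat) * spatial_sd_degC
    } else pat <- matrix(0, cg$n_rows, cg$n_cols)
    fut <- list()
    for (m in 1:12) {
      tn <- sprintf("t_%02d", m); pn <- sprintf("p_%02d", m)
      fut[[tn]] <- make_raster(cg, control$layers[[tn]]$values + dT_mean + pat)
      fut[[pn]] <- make_raster(cg, pmax(control$layers[[pn]]$values * pf_mean,
                                        0))
    }
    out[[k]] <- list(control = control, future = raster_stack(fut))
  }
  out
}

#' Gaussian niche suitability
#'
#' Suitability is `s_max * exp(-sum_v (e_v - mu_v)^2 / (2 sigma_v^2))` over
#' the predictors named in the niche — a smooth unimodal response every SDM
#' family can recover, and the pipeline's ground truth.
#'
#' @param env `tr_stack` holding the niche's predictors.
#' @param niche List with numeric vectors `mu` and `sigma` (named by
#'   predictor) and scalar `s_max` in (0, 1].
#' @return A `tr_raster` of true suitability in (0, s_max].
#' @export
niche_suitability <- function(env, niche) {
  stopifnot(all(names(niche$mu) %in% stack_names(env)),
            all(niche$sigma > 0), niche$s_max > 0, niche$s_max <= 1)
  g <- env$grid
  q <- matrix(0, g$n_rows, g$n_cols)
  for (v in names(niche$mu)) {
    q <- q + (env$layers[[v]]$values - niche$mu[[v]])^2 /
      (2 * niche$sigma[[v]]^2)
  }
  make_raster(g, niche$s_max * exp(-q))
}

#' Sample presence records with spatially biased effort
#'
#' Draws presences cell-wise with probability proportional to true
#' suitability times a per-region sampling intensity, calibrated so the
#' expected record count is about `n_target`; coordinates are jittered
#' uniformly within the cell. This reproduces the uneven inventory effort
#' that spatial thinning is designed to neutralise.
#'
#' @param true_suit `tr_raster` of suitability in [0, 1].
#' @param n_target Target number of records.
#' @param bias_regions List with `region` (integer `tr_raster` of region ids)
#'   and `intensity` (numeric vector indexed by region id). Default: one
#'   region, uniform effort.
#' @param seed Integer seed.
#' @param species_id Species label for the output table.
#' @return Data frame (species_id, x, y, source_tag); zero rows with a
#'   warning if suitability is all zero.
#' @export
sample_occurrences <- function(true_suit, n_target, bias_regions = NULL,
                               seed = 1, species_id = "sp1") {
  g <- true_suit$grid
  set.seed(seed)
  s <- true_suit$values
  s[is.na(s)] <- 0
  if (is.null(bias_regions)) {
    intensity <- matrix(1, g$n_rows, g$n_cols)
  } else {
    ids <- bias_regions$region$values
    intensity <- matrix(bias_regions$intensity[as.integer(ids)],
                        g$n_rows, g$n_cols)
    intensity[is.na(intensity)] <- 0
  }
  w <- s * intensity
  tot <- sum(w)
  if (tot <= 0) {
    warning("sample_occurrences: suitability is zero everywhere; no records")
    return(data.frame(species_id = character(0), x = numeric(0),
                      y = numeric(0), source_tag = character(0)))
  }
  p <- pmin(w * (n_target / tot), 1)
  draw <- matrix(stats::runif(length(p)), nrow(p)) < p
  idx <- which(draw, arr.ind = TRUE)           # row, col
  n <- nrow(idx)
  jx <- stats::runif(n); jy <- stats::runif(n)
  x <- g$origin_x + (idx[, 2] - 1 + jx) * g$cell_size_x
  y <- g$origin_y + (idx[, 1] - 1 + jy) * g$cell_size_y
  data.frame(species_id = species_id, x = x, y = y, source_tag = "synthetic",
             stringsAsFactors = FALSE)
}

#' Synthetic species trait table
#'
#' Dispersal syndrome, seed mass (mg), plant height (m) and terminal
#' velocity (m/s, wind-dispersed only), with an optional expert MDD override
#' column, mirroring the trait inputs of trait-based dispersal models.
#'
#' @param species_ids Character vector.
#' @param seed Integer seed.
#' @return Data frame of traits; `mdd_override_m` is NA unless set by the
#'   caller.
#' @export
make_traits <- function(species_ids, seed = 1) {
  set.seed(seed)
  n <- length(species_ids)
  syndrome <- sample(c("wind", "animal", "none"), n, replace = TRUE)
  seed_mass <- round(10^stats::runif(n, 0, 2.7), 2)      # 1 mg .. 500 mg
  height <- round(stats::runif(n, 8, 40), 1)
  tv <- ifelse(syndrome == "wind", round(stats::runif(n, 0.5, 3), 2), NA)
  data.frame(species_id = species_ids, dispersal_syndrome = syndrome,
             seed_mass_mg = seed_mass, plant_height_m = height,
             terminal_velocity_ms = tv, growth_form = "tree",
             mdd_override_m = NA_real_, stringsAsFactors = FALSE)
}

#' Native-range mask from true suitability
#'
#' A stand-in for expert chorological maps: cells with true suitability at
#' or above `threshold` are native (1), others 0.
#'
#' @param true_suit `tr_raster` in [0, 1].
#' @param threshold Suitability cutoff (default 0.05).
#' @return Binary `tr_raster` in {0, 1}.
#' @export
make_native_mask <- function(true_suit, threshold = 0.05) {
  make_raster(true_suit$grid,
              (true_suit$values >= threshold) + 0, nodata = 255)
}

#' Synthetic land-use fraction stack
#'
#' Eight tree-class cover fractions (needleleaf/broadleaf x evergreen/
#' deciduous x a climatic-region split) plus a non-forest remainder, on a
#' grid finer than the analysis grid by `refine_factor`, with per-cell class
#' sums <= 1. Forest cover follows a smooth field so the 40% threshold
#' produces spatially coherent masks.
#'
#' @param grid Analysis [grid_spec()].
#' @param refine_factor Integer refinement of the land-use grid (default 2).
#' @param seed Integer seed.
#' @param forest_mean Mean total forest fraction (default 0.55).
#' @return A `tr_stack` with the 8 tree-class layers and `non_forest`.
#' @export
make_landuse <- function(grid, refine_factor = 2, seed = 1,
                         forest_mean = 0.55) {
  set.seed(seed)
  fg <- grid_spec(grid$origin_x, grid$origin_y,
                  grid$cell_size_x / refine_factor,
                  grid$cell_size_y / refine_factor,
                  grid$n_cols * refine_factor, grid$n_rows * refine_factor,
                  crs_tag = grid$crs_tag)
  nr <- fg$n_rows; nc <- fg$n_cols
  field <- gaussian_smooth(matrix(stats::rnorm(nr * nc), nr),
                           sigma = max(2, nr / 10))
  field <- (field - mean(field)) / stats::sd(field)
  forest <- pmin(pmax(forest_mean + 0.3 * field, 0), 0.98)
  classes <- tree_landuse_classes()
  share <- matrix(stats::rgamma(length(classes) * nr * nc, shape = 0.6),
                  nrow = length(classes))
  share <- sweep(share, 2, colSums(share), "/")
  layers <- list()
  for (k in seq_along(classes)) {
    layers[[classes[k]]] <-
      make_raster(fg, matrix(forest * share[k, ], nr, nc))
  }
  layers[["non_forest"]] <- make_raster(fg, 1 - forest)
  raster_stack(layers)
}

#' The eight tree land-use class names merged into the forest layer
#' @return Character vector of 8 class names.
#' @export
tree_landuse_classes <- function() {
  c("needleleaf_evergreen_temperate", "needleleaf_evergreen_boreal",
    "needleleaf_deciduous_boreal", "broadleaf_evergreen_tropical",
    "broadleaf_evergreen_temperate", "broadleaf_deciduous_tropical",
    "broadleaf_deciduous_temperate", "broadleaf_deciduous_boreal")
}
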