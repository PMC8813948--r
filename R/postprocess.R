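#' @title Land-use masking, richness and pipeline orchestration
#' @description Forest masking of range maps from fractional land-use
#'   layers, species-richness synthesis, run configuration handling, and
#'   the end-to-end synthetic pipeline that chains occurrence preparation,
#'   climate preparation, the SDM ensemble, dispersal and masking into the
#'   published four-directory output layout.
#' @name postprocess
NULL

#' Binary forest mask from land-use fractions
#'
#' Sums the eight tree-class cover fractions, aggregates the sum to the
#' analysis grid by exact area weighting, and binarizes with a strict
#' threshold: forest where the summed fraction exceeds `threshold`
#' (0.40 by default, so exactly 40% is not forest).
#'
#' @param landuse `tr_stack` of cover fractions including the eight classes
#'   of [tree_landuse_classes()].
#' @param dst_grid Analysis [grid_spec()] (NULL keeps the land-use grid).
#' @param threshold Forest-cover threshold (default 0.40).
#' @param classes Tree-class layer names (default the standard eight).
#' @return Binary `tr_raster` in {0, 1}.
#' @export
forest_mask <- function(landuse, dst_grid = NULL, threshold = 0.40,
                        classes = tree_landuse_classes()) {
  missing_cls <- setdiff(classes, stack_names(landuse))
  if (length(missing_cls))
    stop("forest_mask: land-use stack lacks class(es): ",
         paste(missing_cls, collapse = ", "))
  tot <- Reduce(`+`, lapply(classes, function(cl) landuse$layers[[cl]]$values))
  frac <- make_raster(landuse$grid, tot)
  if (!is.null(dst_grid) && !grids_equal(landuse$grid, dst_grid))
    frac <- aggregate_fraction(frac, dst_grid)
  make_raster(frac$grid, (frac$values > threshold) + 0, nodata = 255)
}

#' Apply a binary mask to a range map
#'
#' Mask-0 cells become 0 on binary/category maps (`how = "zero"`) or NA on
#' probability maps (`how = "nodata"`); mask-1 cells pass unchanged.
#'
#' @param range_map A `tr_raster`.
#' @param mask Binary `tr_raster` on the same grid.
#' @param how `"zero"` or `"nodata"`.
#' @return Masked `tr_raster`.
#' @export
apply_mask <- function(range_map, mask, how = c("zero", "nodata")) {
  how <- match.arg(how)
  if (!grids_equal(range_map$grid, mask$grid))
    stop("apply_mask: grids differ")
  v <- range_map$values
  off <- !is.na(mask$values) & mask$values == 0
  v[off] <- if (how == "zero") 0 else NA
  make_raster(range_map$grid, v, nodata = range_map$nodata)
}

#' Species richness from per-species binary maps
#'
#' Per-cell sum of binaries; a cell is NA only where every input is NA.
#'
#' @param binaries Non-empty list of binary `tr_raster`s on one grid.
#' @return Count `tr_raster`.
#' @export
species_richness <- function(binaries) {
  if (!length(binaries)) stop("species_richness: empty species list")
  g <- binaries[[1]]$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  any_valid <- matrix(FALSE, g$n_rows, g$n_cols)
  for (b in binaries) {
    if (!grids_equal(b$grid, g)) stop("species_richness: grids differ")
    v <- b$values
    any_valid <- any_valid | !is.na(v)
    v[is.na(v)] <- 0
    acc <- acc + v
  }
  acc[!any_valid] <- NA
  make_raster(g, acc, nodata = 255)
}

# ---- run configuration --------------------------------------------------

#' Default synthetic-run configuration
#'
#' Flat key-value configuration for the end-to-end pipeline; every
#' threshold of the method is audited here. `rcp85` pairs with the "ssp5"
#' land-use tag by default (configurable).
#'
#' @param seed Master seed; stage seeds are derived from it.
#' @return Named list of class `run_config`.
#' @export
default_run_config <- function(seed = 1) {
  structure(list(
    scenario = "rcp45", ssp_tag = "ssp2",
    periods = c(2035, 2065, 2095),
    ensemble_mode = "both",           # climatic_ensemble, sdm_ensemble, both
    n_species = 3, n_rcms = 3,
    n_cols = 100, n_rows = 120, cell_size_m = 10000,
    coarsen_factor = 4,
    warming_mean_degC = 3, precip_factor_mean = 0.9,
    n_occurrences = 4000, n_pseudoabsences = 2000,
    block_km = 40, min_n = 30,
    sre_q = 0.025, vif_threshold = 10,
    eps_mm = 0.1, ratio_cap = 10,
    tss_floor = 0.7, min_valid = 2,
    cv_block_km = 120, cv_k = 5,
    forest_threshold = 0.40,
    n_replicates = 10,
    seed = seed), class = "run_config")
}

#' Write a run configuration as a flat key-value text file
#' @param config A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(k)
    paste0(k, " = ", paste(config[[k]], collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration written by [write_run_config()]
#' @param path Config file path.
#' @return A `run_config` (numeric fields restored).
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  base <- default_run_config()
  out <- list()
  for (ln in lines[nzchar(trimws(lines))]) {
    kv <- strsplit(ln, "\\s*=\\s*")[[1]]
    vals <- strsplit(kv[2], ",")[[1]]
    num <- suppressWarnings(as.numeric(vals))
    out[[kv[1]]] <- if (!anyNA(num)) num else vals
  }
  for (k in names(base)) if (is.null(out[[k]])) out[[k]] <- base[[k]]
  structure(out[names(base)], class = "run_config")
}

# ---- end-to-end pipeline ------------------------------------------------

#' Run the full synthetic pipeline
#'
#' Generates a synthetic world with known species niches, then runs the
#' whole chain for each species: occurrence preparation (dedupe, native-
#' range trim, >= min_n filter, 40 km thinning), predictor derivation and
#' collinearity screening, SRE pseudo-absences, six-family fitting, block
#' cross-validation, TSS-floored consensus, change-factor downscaled future
#' projections per pseudo-RCM (both ensemble modes), dispersal simulation,
#' and land-use masking, writing the published four-directory layout
#' (`ens_clim/`, `ens_sdms/`, `single_models/{bin,prob,CV}/`, `datasets/`)
#' plus a machine-readable run report.
#'
#' @param config A `run_config` (see [default_run_config()]).
#' @param out_dir Output directory (NULL skips all file writing).
#' @param quiet Suppress progress messages.
#' @return List of class `pipeline_result`: per-species results (`species`),
#'   the run `report` (TSS and importance tables, exclusions, seeds), and
#'   shared inputs (`world`, `env_now`, grids).
#' @export
run_pipeline <- function(config = default_run_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  stopifnot(inherits(config, "run_config"))
  seed <- config$seed
  t0 <- Sys.time()

  say("[world] generating %dx%d synthetic world", config$n_rows, config$n_cols)
  world <- make_world(config$n_cols, config$n_rows, config$cell_size_m,
                      seed = seed)
  grid <- world$grid
  env_now <- derive_bioclim(world)

  # pseudo-RCM ensemble and downscaled future predictor stacks
  say("[climate] %d pseudo-RCMs, change-factor downscaling", config$n_rcms)
  rcms <- make_future(world, n_models = config$n_rcms,
                      warming_mean_degC = config$warming_mean_degC,
                      precip_factor_mean = config$precip_factor_mean,
                      coarsen_factor = config$coarsen_factor,
                      seed = seed + 1)
  # per period, interpolate the warming linearly toward the end-of-century
  # anomaly so the three periods form a monotone pathway
  period_frac <- seq_along(config$periods) / length(config$periods)
  future_envs <- list()   # [[period]][[rcm]]
  for (pi in seq_along(config$periods)) {
    fr <- period_frac[pi]
    envs <- lapply(rcms, function(rc) {
      fut <- rc$future
      scaled <- list()
      for (nm in stack_names(fut)) {
        cv <- rc$control$layers[[nm]]$values
        fv <- fut$layers[[nm]]$values
        scaled[[nm]] <- make_raster(fut$grid, cv + fr * (fv - cv))
      }
      derive_bioclim(change_factor_downscale(world, rc$control,
                                             raster_stack(scaled),
                                             eps_mm = config$eps_mm,
                                             ratio_cap = config$ratio_cap))
    })
    future_envs[[as.character(config$periods[pi])]] <- envs
  }

  # land use and forest mask for the final period
  landuse <- make_landuse(grid, refine_factor = 2, seed = seed + 2)
  fmask <- forest_mask(landuse, dst_grid = grid,
                       threshold = config$forest_threshold)

  # species niches spanning the climate space
  set.seed(seed + 3)
  species <- list()
  for (s in seq_len(config$n_species)) {
    mat_rng <- range(env_now$layers$Mat$values)
    mu_mat <- stats::runif(1, mat_rng[1] + 0.25 * diff(mat_rng),
                           mat_rng[1] + 0.75 * diff(mat_rng))
    ptot_rng <- range(env_now$layers$Ptot$values)
    mu_ptot <- stats::runif(1, ptot_rng[1] + 0.25 * diff(ptot_rng),
                            ptot_rng[1] + 0.75 * diff(ptot_rng))
    species[[paste0("sp", s)]] <- list(
      mu = c(Mat = mu_mat, Ptot = mu_ptot),
      sigma = c(Mat = 0.10 * diff(mat_rng), Ptot = 0.10 * diff(ptot_rng)),
      s_max = 0.95)
  }
  traits <- make_traits(names(species), seed = seed + 4)

  # biased sampling effort: west/east halves at 4:1 intensity
  region <- make_raster(grid, matrix(rep(c(1, 2),
                                         times = c(floor(grid$n_cols / 2),
                                                   ceiling(grid$n_cols / 2))),
                                     grid$n_rows, grid$n_cols, byrow = TRUE))
  bias <- list(region = region, intensity = c(4, 1))

  report <- list(config = unclass(config), tss = list(), importance = list(),
                 excluded = character(0), unmodellable = character(0),
                 seeds = c(master = seed))
  results <- list()

  for (sp in names(species)) {
    say("[species %s] sampling + preparation", sp)
    res <- tryCatch({
      truth <- niche_suitability(env_now, species[[sp]])
      occ <- sample_occurrences(truth, config$n_occurrences, bias,
                                seed = seed + 10 + match(sp, names(species)),
                                species_id = sp)
      mask_nat <- make_native_mask(truth, threshold = 0.05)
      prep <- prep_occurrences(occ, grid, masks = stats::setNames(
        list(mask_nat), sp), block_size = config$block_km * 1000,
        min_n = config$min_n, seed = seed + 20)
      if (nrow(prep$occ) < config$min_n) {
        report$excluded <- c(report$excluded, sp)
        stop("too few occurrences after preparation")
      }

      pres_env <- stack_extract(env_now, prep$occ$x, prep$occ$y)
      vif_keep <- vif_screen(pres_env[stats::complete.cases(pres_env), ],
                             threshold = config$vif_threshold)
      env_sel <- raster_stack(env_now$layers[vif_keep])

      sre <- build_sre(pres_env[, intersect(climatic_predictors(), vif_keep),
                                drop = FALSE], q = config$sre_q)
      pa <- sample_pseudoabsences(env_sel, sre, n = config$n_pseudoabsences,
                                  seed = seed + 30)
      pa_env <- stack_extract(env_now, pa$x, pa$y, layers = vif_keep)
      cal <- make_calibration(pres_env[, vif_keep, drop = FALSE], pa_env,
                              presence_xy = prep$occ[, c("x", "y")],
                              absence_xy = pa)

      say("[species %s] fitting 6 families + block CV", sp)
      members <- fit_members(cal, seed = seed + 40)
      cv <- block_cross_validate(cal, block_size_m = config$cv_block_km * 1000,
                                 k = config$cv_k, seed = seed + 50,
                                 anchor = c(grid$origin_x, grid$origin_y))
      members <- set_member_tss(members, cv)
      report$tss[[sp]] <- cv

      ens <- consensus(members, env_sel, cal, tss_floor = config$tss_floor)

      say("[species %s] variable importance", sp)
      imp_idx <- sample.int(nrow(cal$data), min(500, nrow(cal$data)))
      imp <- variable_importance(consensus_predict_fun(ens$members),
                                 cal$data[imp_idx, , drop = FALSE],
                                 n_rep = 10, seed = seed + 60)
      report$importance[[sp]] <- imp

      say("[species %s] future projections + dispersal", sp)
      ref_env <- cal$data
      modes <- if (config$ensemble_mode == "both")
        c("climatic_ensemble", "sdm_ensemble") else config$ensemble_mode
      projections <- list()
      suit_series <- list()
      for (per in as.character(config$periods)) {
        envs_p <- lapply(future_envs[[per]],
                         function(e) raster_stack(e$layers[vif_keep]))
        projections[[per]] <- lapply(stats::setNames(modes, modes),
          function(md) project_future(ens, envs_p, mode = md,
                                      min_valid = config$min_valid,
                                      reference_env = ref_env))
        first_mode <- modes[1]
        bin <- projections[[per]][[first_mode]]$binary
        v <- bin$values; v[is.na(v)] <- 0
        suit_series[[per]] <- make_raster(grid, v, nodata = 255)
      }

      mdd <- predict_mdd(traits[traits$species_id == sp, ])
      dp <- dispersal_params(mdd = max(mdd, 1.5 * config$cell_size_m),
                             n_replicates = config$n_replicates)
      init <- apply_mask(ens$binary, mask_nat, how = "zero")
      disp <- run_dispersal(init, suit_series, dp, seed = seed + 70)

      masked_final <- apply_mask(disp$occupied_majority, fmask, how = "zero")
      masked_suit <- apply_mask(suit_series[[length(suit_series)]], fmask,
                                how = "zero")

      list(species = sp, truth = truth, prep = prep, vif_keep = vif_keep,
           members = members, cv = cv, ensemble = ens,
           importance = imp, projections = projections,
           dispersal = disp, dispersal_params = dp, native_mask = mask_nat,
           masked_final = masked_final, masked_suitability = masked_suit)
    }, error = function(e) {
      say("[species %s] FAILED: %s", sp, conditionMessage(e))
      report$unmodellable <<- c(report$unmodellable, sp)
      NULL
    })
    results[[sp]] <- res
  }

  ok <- Filter(Negate(is.null), results)
  if (length(ok)) {
    report$richness_now <- species_richness(
      lapply(ok, function(r) r$ensemble$binary))
  }
  report$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))

  out <- structure(list(species = results, report = report, world = world,
                        env_now = env_now, grid = grid,
                        forest_mask = fmask, traits = traits,
                        config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Write pipeline outputs in the published directory layout
#'
#' `ens_clim/` (binary maps from the climatic-ensemble mode), `ens_sdms/`
#' (binary + probability + sd from the SDM-ensemble mode), `single_models/`
#' (`bin`, `prob`, `CV` per species for the current period) and `datasets/`
#' (prepared occurrences, traits, config echo, TSS and importance tables).
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  for (d in c("ens_clim", "ens_sdms", file.path("single_models", "bin"),
              file.path("single_models", "prob"),
              file.path("single_models", "CV"), "datasets", "dispersal")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  cfg <- result$config
  write_run_config(cfg, file.path(out_dir, "datasets", "run.cfg"))
  utils::write.csv(result$traits,
                   file.path(out_dir, "datasets", "traits.csv"),
                   row.names = FALSE)
  tss_rows <- list(); imp_rows <- list()
  for (sp in names(result$species)) {
    r <- result$species[[sp]]
    if (is.null(r)) next
    scen <- cfg$scenario
    utils::write.csv(r$prep$occ,
                     file.path(out_dir, "datasets",
                               paste0(sp, "_occurrences.csv")),
                     row.names = FALSE)
    write_ascii_grid(r$ensemble$binary,
                     file.path(out_dir, "single_models", "bin",
                               paste0(sp, "_", scen, "_current_bin.asc")))
    write_ascii_grid(r$ensemble$consensus_prob,
                     file.path(out_dir, "single_models", "prob",
                               paste0(sp, "_", scen, "_current_prob.asc")))
    write_ascii_grid(r$ensemble$member_dispersion,
                     file.path(out_dir, "single_models", "CV",
                               paste0(sp, "_", scen, "_current_cv.asc")))
    for (per in names(r$projections)) {
      pj <- r$projections[[per]]
      if ("climatic_ensemble" %in% names(pj)) {
        write_ascii_grid(pj$climatic_ensemble$binary,
                         file.path(out_dir, "ens_clim",
                                   paste0(sp, "_", scen, "_", per,
                                          "_bin.asc")))
      }
      if ("sdm_ensemble" %in% names(pj)) {
        p <- pj$sdm_ensemble
        base <- file.path(out_dir, "ens_sdms",
                          paste0(sp, "_", scen, "_", per))
        write_ascii_grid(p$binary, paste0(base, "_bin.asc"))
        write_ascii_grid(p$prob, paste0(base, "_prob.asc"))
        write_ascii_grid(p$sd, paste0(base, "_sd.asc"))
      }
    }
    write_ascii_grid(r$dispersal$occupancy_freq,
                     file.path(out_dir, "dispersal",
                               paste0(sp, "_", scen, "_freq.asc")))
    write_ascii_grid(r$dispersal$category,
                     file.path(out_dir, "dispersal",
                               paste0(sp, "_", scen, "_category.asc")))
    tss_rows[[sp]] <- cbind(species = sp, r$cv)
    imp_rows[[sp]] <- cbind(species = sp, r$importance)
  }
  if (length(tss_rows))
    utils::write.csv(do.call(rbind, tss_rows),
                     file.path(out_dir, "datasets", "tss_table.csv"),
                     row.names = FALSE)
  if (length(imp_rows))
    utils::write.csv(do.call(rbind, imp_rows),
                     file.path(out_dir, "datasets", "importance_table.csv"),
                     row.names = FALSE)
  rep_json <- list(
    scenario = cfg$scenario, ssp_tag = cfg$ssp_tag, seed = cfg$seed,
    excluded = result$report$excluded,
    unmodellable = result$report$unmodellable,
    elapsed_s = result$report$elapsed_s)
  jsonlite::write_json(rep_json, file.path(out_dir, "datasets",
                                           "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
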