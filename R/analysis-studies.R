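#' @title Standard synthetic studies
#' @description Packaged study designs used by the analysis scripts and the
#'   acceptance checks: a parameter-recovery study on one synthetic species
#'   with known Gaussian niche, run under the pipeline's standard
#'   calibration design.
#' @name analysis-studies
NULL

#' Parameter-recovery study on a synthetic Gaussian-niche species
#'
#' Builds a 100 x 120 synthetic world, defines one species with a Gaussian
#' niche on mean annual temperature and total annual precipitation
#' (breadth 0.10 of the within-domain predictor range, a restricted-range
#' species), samples occurrences with 4:1 west/east effort bias, prepares
#' them (dedupe, 40 km thinning, >= 30 filter), screens predictors by VIF,
#' draws pseudo-absences outside the climatic envelope, fits the six
#' families, block cross-validates them, forms the TSS-floored consensus,
#' and measures recovery against the known truth.
#'
#' @param seed Integer master seed.
#' @param n_cols,n_rows Grid dimensions (default 100 x 120).
#' @param n_occurrences Target raw occurrence count before preparation.
#' @param n_pseudoabsences Pseudo-absence count (default 2000).
#' @param n_importance_runs Seeded repeats of the permutation-importance
#'   procedure (default 10).
#' @param quiet Suppress progress messages.
#' @return List: `cv` (per-family block-CV TSS), `consensus_truth_r`
#'   (Pearson r of consensus probability vs true suitability over the
#'   grid), `importance_runs` (list of importance tables),
#'   `decoy_last_runs` (how many runs rank an unused predictor last),
#'   `n_presences`, `retained`, plus the underlying objects.
#' @export
parameter_recovery_study <- function(seed = 1, n_cols = 100, n_rows = 120,
                                     n_occurrences = 4000,
                                     n_pseudoabsences = 2000,
                                     n_importance_runs = 10,
                                     quiet = TRUE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("[recovery] world + species")
  world <- make_world(n_cols, n_rows, seed = seed)
  env <- derive_bioclim(world)
  grid <- env$grid
  mat_r <- range(env$layers$Mat$values)
  ptot_r <- range(env$layers$Ptot$values)
  niche <- list(mu = c(Mat = mean(mat_r), Ptot = mean(ptot_r)),
                sigma = c(Mat = 0.10 * diff(mat_r),
                          Ptot = 0.10 * diff(ptot_r)),
                s_max = 0.95)
  truth <- niche_suitability(env, niche)

  region <- make_raster(grid, matrix(rep(c(1, 2),
                                         times = c(floor(grid$n_cols / 2),
                                                   ceiling(grid$n_cols / 2))),
                                     grid$n_rows, grid$n_cols, byrow = TRUE))
  occ <- sample_occurrences(truth, n_occurrences,
                            bias_regions = list(region = region,
                                                intensity = c(4, 1)),
                            seed = seed + 1)
  prep <- prep_occurrences(occ, grid, seed = seed + 2)

  say("[recovery] predictors + calibration (%d presences)", nrow(prep$occ))
  pres_env <- stack_extract(env, prep$occ$x, prep$occ$y)
  keep <- vif_screen(pres_env, threshold = 10)
  env_sel <- raster_stack(env$layers[keep])
  sre <- build_sre(pres_env[, intersect(climatic_predictors(), keep),
                            drop = FALSE], q = 0.025)
  pa <- sample_pseudoabsences(env_sel, sre, n = n_pseudoabsences,
                              seed = seed + 3)
  pa_env <- stack_extract(env, pa$x, pa$y, layers = keep)
  cal <- make_calibration(pres_env[, keep, drop = FALSE], pa_env,
                          presence_xy = prep$occ[, c("x", "y")],
                          absence_xy = pa)

  say("[recovery] fitting + block cross-validation")
  members <- fit_members(cal, seed = seed + 4)
  cv <- block_cross_validate(cal, block_size_m = 120000, k = 5,
                             seed = seed + 5,
                             anchor = c(grid$origin_x, grid$origin_y))
  members <- set_member_tss(members, cv)
  ens <- consensus(members, env_sel, cal, tss_floor = 0.7)
  r <- stats::cor(as.vector(t(ens$consensus_prob$values)) / 1000,
                  as.vector(t(truth$values)))

  say("[recovery] permutation importance (%d runs)", n_importance_runs)
  unused <- setdiff(keep, names(niche$mu))
  set.seed(seed + 6)
  idx <- sample.int(nrow(cal$data), min(300, nrow(cal$data)))
  sample_env <- cal$data[idx, , drop = FALSE]
  pf <- consensus_predict_fun(ens$members)
  importance_runs <- lapply(seq_len(n_importance_runs), function(k)
    variable_importance(pf, sample_env, n_rep = 10, seed = seed + 100 + k))
  decoy_last <- vapply(importance_runs, function(imp)
    imp$predictor[which.min(imp$importance)] %in% unused, logical(1))

  list(cv = cv, consensus_truth_r = r,
       importance_runs = importance_runs,
       decoy_last_runs = sum(decoy_last),
       n_importance_runs = n_importance_runs,
       n_presences = nrow(prep$occ), retained = ens$retained_members,
       unused_predictors = unused, vif_keep = keep,
       niche = niche, truth = truth, env = env_sel, cal = cal,
       members = members, ensemble = ens)
}
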