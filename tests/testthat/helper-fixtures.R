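# shared fixture builders; everything is generated in code at test time

tiny_grid <- function(n_cols = 3, n_rows = 3, cell = 10000, crs = "local") {
  grid_spec(0, n_rows * cell, cell, -cell, n_cols, n_rows, crs_tag = crs)
}

# small world + derived predictors, cached per session
fixture_env <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- make_world(40, 40, seed = 11)
      cache <<- list(world = w, env = derive_bioclim(w))
    }
    cache
  }
})

# a calibration set for a recoverable 2-predictor niche on the small world
fixture_calibration <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      fx <- fixture_env()
      env <- fx$env
      mat_r <- range(env$layers$Mat$values)
      ptot_r <- range(env$layers$Ptot$values)
      niche <- list(mu = c(Mat = mean(mat_r), Ptot = mean(ptot_r)),
                    sigma = c(Mat = 0.12 * diff(mat_r),
                              Ptot = 0.12 * diff(ptot_r)),
                    s_max = 0.95)
      truth <- niche_suitability(env, niche)
      occ <- sample_occurrences(truth, 1200, seed = 12)
      prep <- prep_occurrences(occ, env$grid, seed = 13)
      pres_env <- stack_extract(env, prep$occ$x, prep$occ$y)
      sre <- build_sre(pres_env[, climatic_predictors()], q = 0.025)
      pa <- sample_pseudoabsences(env, sre, n = 600, seed = 14)
      pa_env <- stack_extract(env, pa$x, pa$y)
      cal <- make_calibration(pres_env, pa_env,
                              presence_xy = prep$occ[, c("x", "y")],
                              absence_xy = pa)
      cache <<- list(env = env, truth = truth, cal = cal, sre = sre,
                     niche = niche)
    }
    cache
  }
})

# linearly separable calibration set on one predictor
separable_calibration <- function(n = 200, seed = 1) {
  set.seed(seed)
  pres <- data.frame(a = stats::rnorm(n, 3, 0.5),
                     b = stats::rnorm(n, 0, 1))
  abs_ <- data.frame(a = stats::rnorm(5 * n, -3, 0.5),
                     b = stats::rnorm(5 * n, 0, 1))
  make_calibration(pres, abs_,
                   presence_xy = cbind(x = stats::runif(n, 0, 1e5),
                                       y = stats::runif(n, 0, 1e5)),
                   absence_xy = cbind(x = stats::runif(5 * n, 0, 1e5),
                                      y = stats::runif(5 * n, 0, 1e5)))
}
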