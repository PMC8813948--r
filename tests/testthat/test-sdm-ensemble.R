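test_that("the surface range envelope follows presence quantiles", {
  set.seed(71)
  pres <- cbind(a = stats::runif(400), b = stats::rnorm(400))
  sre0 <- build_sre(pres, q = 0)
  expect_equal(unclass(sre0)["lower", "a"], min(pres[, "a"]))
  expect_equal(unclass(sre0)["upper", "b"], max(pres[, "b"]))
  expect_true(all(sre_inside(sre0, pres)))

  sre <- build_sre(pres, q = 0.025)
  frac_in <- mean(sre_inside(sre, pres))
  expect_gt(frac_in, 0.88)
  expect_lt(frac_in, 0.98)

  # violating a single predictor suffices to be outside
  probe <- cbind(a = 0.5, b = 100)
  expect_false(sre_inside(sre, probe))

  expect_error(build_sre(pres, q = 0.6), "q")
})

test_that("pseudo-absences fall outside the envelope, with shortfall reporting", {
  fxc <- fixture_calibration()
  env <- fxc$env
  pa <- sample_pseudoabsences(env, fxc$sre, n = 300, seed = 72)
  pa_env <- stack_extract(env, pa$x, pa$y,
                          layers = colnames(unclass(fxc$sre)))
  expect_false(any(sre_inside(fxc$sre, pa_env)))
  expect_identical(attr(pa, "shortfall"), 0L)

  # exhaustion: more requested than candidates exist
  pa_all <- sample_pseudoabsences(env, fxc$sre, n = 10^6, seed = 73)
  expect_gt(attr(pa_all, "shortfall"), 0L)

  # an envelope covering nothing makes every valid cell a candidate
  tiny_sre <- structure(rbind(lower = c(Mat = 1e5), upper = c(Mat = 1e5 + 1)),
                        class = "sre_envelope")
  pa_none <- sample_pseudoabsences(env, tiny_sre, n = 10^6, seed = 74)
  expect_identical(nrow(pa_none),
                   env$grid$n_rows * env$grid$n_cols)
})

test_that("TSS arithmetic matches the confusion-table definition", {
  # hand-computed: tp=40, fn=10, tn=30, fp=20
  scores <- c(rep(900, 40), rep(100, 10), rep(100, 30), rep(900, 20))
  labels <- c(rep(1, 50), rep(0, 50))
  rep_ <- tss_at_threshold(scores, labels, 500)
  expect_equal(rep_$sensitivity, 0.8)
  expect_equal(rep_$specificity, 0.6)
  expect_equal(rep_$tss, 0.4)
  expect_equal(rep_$tss, rep_$sensitivity + rep_$specificity - 1)

  # perfect separation and the no-skill case
  expect_equal(tss_at_threshold(c(800, 800, 200), c(1, 1, 0), 500)$tss, 1)
  expect_equal(tss_at_threshold(c(700, 300, 700, 300), c(1, 1, 0, 0),
                                500)$tss, 0)
  expect_error(tss_at_threshold(c(1, 2), c(1, 1), 1), "both classes")
})

test_that("optimal_threshold ties break low and match the brute-force scan", {
  expect_identical(optimal_threshold(c(800, 800, 200, 200), c(1, 1, 0, 0)),
                   201L)
  set.seed(75)
  for (i in 1:5) {
    sc <- sample(0:1000, 200, replace = TRUE)
    lab <- stats::rbinom(200, 1, stats::plogis((sc - 500) / 200))
    if (length(unique(lab)) < 2) next
    brute <- vapply(0:1000, function(t)
      tss_at_threshold(sc, lab, t)$tss, numeric(1))
    expect_identical(optimal_threshold(sc, lab),
                     as.integer(which.max(brute) - 1L))
  }

  # order-preserving relabeling of scores keeps the optimal classification
  sc <- c(10, 300, 500, 900)
  lab <- c(0, 0, 1, 1)
  t1 <- optimal_threshold(sc, lab)
  sc2 <- as.integer(round(1000 * (sc / 1000)^0.5))
  t2 <- optimal_threshold(sc2, lab)
  expect_identical(sc >= t1, sc2 >= t2)
})

test_that("block cross-validation partitions blocks and detects degeneracy", {
  cal <- separable_calibration(n = 150, seed = 76)
  # all data in one block: insufficient blocks for k folds
  cal_one <- cal
  cal_one$xy <- cbind(x = rep(10, nrow(cal$data)),
                      y = rep(10, nrow(cal$data)))
  expect_error(block_cross_validate(cal_one, 1e6, k = 5), "blocks")

  cv <- block_cross_validate(cal, block_size_m = 2e4, k = 5, seed = 77,
                             families = "glm")
  expect_identical(cv$n_folds_used + cv$n_folds_skipped, 5L)
  expect_gte(cv$cv_tss, 0.9)   # separable species recovers near-perfectly
})

test_that("consensus averages retained members and excludes weak ones", {
  fxc <- fixture_calibration()
  cal <- fxc$cal
  members <- fit_members(cal, families = c("glm", "gam"), seed = 78)
  members$glm$cv_tss <- 0.9
  members$gam$cv_tss <- 0.9
  env <- fxc$env
  ens <- consensus(members, env, cal, tss_floor = 0.7)
  expect_identical(sort(ens$retained_members), c("gam", "glm"))

  # one retained member: consensus equals that member, dispersion 0
  members1 <- members
  members1$gam$cv_tss <- 0.1
  ens1 <- consensus(members1, env, cal, tss_floor = 0.7)
  expect_identical(ens1$retained_members, "glm")
  solo <- predict_prob(members$glm, env)
  expect_identical(ens1$consensus_prob$values, round(solo$values))
  expect_true(all(ens1$member_dispersion$values[solo$values > 0] == 0))

  # dropping a member changes the consensus the way direct recomputation says
  m_glm <- predict_prob(members$glm, env)$values
  m_gam <- predict_prob(members$gam, env)$values
  expect_identical(ens$consensus_prob$values, round((m_glm + m_gam) / 2))

  # two members scoring 400 and 600 at a cell: mean 500, cv = sd/mean
  expect_equal(stats::sd(c(400, 600)) / 500, 0.2828, tolerance = 1e-3)

  # no member above the floor: unmodellable
  members0 <- members
  members0$glm$cv_tss <- 0.2; members0$gam$cv_tss <- 0.2
  expect_error(consensus(members0, env, cal, 0.7), "unmodellable")

  # binary equals thresholded consensus
  expect_identical(ens$binary$values,
                   (ens$consensus_prob$values >= ens$tss_threshold) + 0)
})

test_that("permutation importance isolates used and unused predictors", {
  set.seed(79)
  n <- 400
  env <- data.frame(a = stats::rnorm(n), b = stats::rnorm(n))
  # model = identity on predictor a, ignores b
  pf <- function(nd) stats::plogis(3 * nd$a)
  imp <- variable_importance(pf, env, n_rep = 10, seed = 80)
  expect_lt(abs(imp$importance[imp$predictor == "b"]), 0.05)
  expect_gt(imp$importance[imp$predictor == "a"], 0.8)

  # seed-reproducible
  imp2 <- variable_importance(pf, env, n_rep = 10, seed = 80)
  expect_identical(imp, imp2)

  # constant predictions: flagged, importance 0
  impc <- variable_importance(function(nd) rep(0.5, nrow(nd)), env,
                              n_rep = 3, seed = 81)
  expect_true(all(impc$flagged))
  expect_true(all(impc$importance == 0))
})

test_that("MESS matches its case table and the sign convention", {
  g <- tiny_grid(1, 3, cell = 10)
  ref <- cbind(v = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10))
  probe_vals <- matrix(c(5.5, 0.5, 10.5), 3, 1)   # median, below-min, above-max
  env <- raster_stack(list(v = make_raster(g, probe_vals)))
  ms <- mess(ref, env)
  expect_equal(ms$values[1, 1], 100)               # f = 50 => 2*50
  expect_lt(ms$values[2, 1], 0)                    # extrapolation below min
  expect_lt(ms$values[3, 1], 0)                    # extrapolation above max

  # a zero-range reference predictor: 100 at the constant, 0 elsewhere
  ref2 <- cbind(v = rep(4, 5))
  env2 <- raster_stack(list(v = make_raster(g, matrix(c(4, 3, 5), 3, 1))))
  ms2 <- mess(ref2, env2)
  expect_equal(as.vector(ms2$values), c(100, 0, 0))
})

test_that("MESS equals the brute-force percentile oracle and is >= 0 on itself", {
  set.seed(82)
  ref <- cbind(a = stats::rnorm(20), b = stats::runif(20))
  g <- grid_spec(0, 100, 10, -10, 10, 10)
  env <- raster_stack(list(a = make_raster(g, matrix(stats::rnorm(100), 10)),
                           b = make_raster(g, matrix(stats::runif(100, -0.5,
                                                                  1.5), 10))))
  got <- mess(ref, env)
  m <- stack_as_matrix(env)
  oracle_sim <- function(rv, p) {
    f <- 100 * sum(rv < p) / length(rv)
    mn <- min(rv); mx <- max(rv)
    if (f == 0) 100 * (p - mn) / (mx - mn)
    else if (f <= 50) 2 * f
    else if (f < 100) 2 * (100 - f)
    else 100 * (mx - p) / (mx - mn)
  }
  want <- apply(m, 1, function(row)
    min(oracle_sim(ref[, "a"], row["a"]), oracle_sim(ref[, "b"], row["b"])))
  expect_equal(as.vector(t(got$values)), as.vector(want))

  # reference probed against itself is never negative
  gref <- grid_spec(0, 40, 10, -10, 5, 4)
  env_ref <- raster_stack(list(a = make_raster(gref, matrix(ref[, "a"], 4, 5)),
                               b = make_raster(gref, matrix(ref[, "b"], 4, 5))))
  expect_gte(min(mess(ref, env_ref)$values), 0)
})

test_that("future projection modes agree on identical runs and apply 8-of-11", {
  fxc <- fixture_calibration()
  cal <- fxc$cal
  members <- fit_members(cal, families = c("glm", "mars"), seed = 83)
  members$glm$cv_tss <- members$mars$cv_tss <- 0.9
  env <- fxc$env
  ens <- consensus(members, env, cal, 0.7)

  futures <- rep(list(env), 11)
  pc <- project_future(ens, futures, mode = "climatic_ensemble")
  ps <- project_future(ens, futures, mode = "sdm_ensemble", min_valid = 8)
  expect_identical(pc$prob$values, ps$prob$values)
  expect_true(all(ps$sd$values[!is.na(ps$sd$values)] == 0))
  expect_identical(pc$binary$values, ps$binary$values)

  # a cell valid in only 7 of 11 runs becomes nodata under min_valid = 8
  futures2 <- futures
  for (k in 1:4) futures2[[k]]$layers$Mat$values[2, 2] <- NA
  ps2 <- project_future(ens, futures2, mode = "sdm_ensemble", min_valid = 8)
  expect_identical(ps2$n_valid$values[2, 2], 7L)
  expect_true(is.na(ps2$prob$values[2, 2]))
  expect_false(is.na(ps2$prob$values[3, 3]))

  # the per-cell mean equals a brute-force average of member projections
  maps <- lapply(futures, function(e) {
    arr <- (predict_prob(members$glm, e)$values +
              predict_prob(members$mars, e)$values) / 2
    round(arr)
  })
  brute <- round(Reduce(`+`, maps) / length(maps))
  expect_identical(ps$prob$values, brute)

  expect_error(project_future(ens, futures[1:5], mode = "sdm_ensemble",
                              min_valid = 8), "min_valid")
})
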