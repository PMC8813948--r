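constant_clim <- function(g, t = 10, p = 50) {
  layers <- list()
  for (m in 1:12) {
    layers[[sprintf("t_%02d", m)]] <- make_raster(g, t)
    layers[[sprintf("p_%02d", m)]] <- make_raster(g, p)
  }
  raster_stack(layers)
}

test_that("bioclim derivation matches closed forms on constant climate", {
  g <- tiny_grid(3, 3)
  env <- derive_bioclim(constant_clim(g, t = 10, p = 50))
  expect_true(all(env$layers$Mat$values == 10))
  expect_true(all(env$layers$Ts$values == 10))
  expect_true(all(env$layers$Pw$values == 50))
  expect_true(all(env$layers$Ps$values == 50))
  expect_true(all(env$layers$Ptot$values == 600))
  expect_true(all(env$layers$Pse$values == 0))
  expect_true(all(env$layers$Ci$values == 0))
})

test_that("bioclim derivation handles single-month spikes correctly", {
  g <- tiny_grid(2, 2)
  clim <- constant_clim(g, t = 0, p = 0)
  clim$layers$t_07 <- make_raster(g, 12)     # July-only warmth
  env <- derive_bioclim(clim)
  expect_true(all(env$layers$Ci$values == 12))
  expect_true(all(env$layers$Mat$values == 1))

  clim2 <- constant_clim(g, t = 5, p = 0)
  clim2$layers$p_01 <- make_raster(g, 100)   # January-only rain
  env2 <- derive_bioclim(clim2)
  expect_true(all(env2$layers$Ptot$values == 100))
  expect_equal(env2$layers$Pw$values[1, 1], 100 / 3)
  expect_true(all(env2$layers$Ps$values == 0))

  # a missing month is a format error
  broken <- constant_clim(g)
  broken$layers$t_05 <- NULL
  expect_error(derive_bioclim(raster_stack(broken$layers)), "t_05")
})

test_that("VIF screening drops collinear layers and keeps independent ones", {
  set.seed(61)
  n <- 400
  a <- stats::rnorm(n); b <- stats::rnorm(n)
  keep <- vif_screen(cbind(a = a, b = b), threshold = 10)
  expect_identical(keep, c("a", "b"))

  # an exact copy: the later-listed duplicate is dropped first
  keep2 <- vif_screen(cbind(a = a, b = b, a2 = a), threshold = 10)
  expect_identical(keep2, c("a", "b"))

  # an exact linear combination is dropped; survivors' VIFs < 10
  # (oracle: VIF = 1/(1-R^2) from explicit OLS)
  cmb <- 2 * a - 3 * b
  keep3 <- vif_screen(cbind(a = a, b = b, cmb = cmb), threshold = 10)
  expect_identical(keep3, c("a", "b"))
  for (j in 1:2) {
    m <- cbind(a, b)
    r2 <- summary(stats::lm(m[, j] ~ m[, -j]))$r.squared
    expect_lt(1 / (1 - r2), 10)
  }
})

test_that("VIF screening is invariant to affine rescaling of a layer", {
  set.seed(62)
  n <- 300
  x <- cbind(a = stats::rnorm(n), b = stats::rnorm(n))
  x <- cbind(x, c = 0.9 * x[, "a"] + 0.1 * stats::rnorm(n))
  colnames(x) <- c("a", "b", "c")
  x2 <- x
  x2[, "c"] <- 100 * x2[, "c"] - 7
  expect_identical(vif_screen(x, 5), vif_screen(x2, 5))
})

test_that("change-factor downscaling: identity, uniform delta, uniform ratio", {
  fine_g <- grid_spec(0, 80, 10, -10, 8, 8)
  coarse_g <- grid_spec(0, 80, 40, -40, 2, 2)
  baseline <- constant_clim(fine_g, t = 8, p = 60)
  control <- constant_clim(coarse_g, t = 9, p = 40)

  # future == control reproduces the baseline exactly
  out0 <- change_factor_downscale(baseline, control, control)
  expect_equal(out0$layers$t_04$values, baseline$layers$t_04$values)
  expect_equal(out0$layers$p_04$values, baseline$layers$p_04$values)

  # uniform +3 warming and 1.5x precipitation
  future <- constant_clim(coarse_g, t = 12, p = 60)
  out <- change_factor_downscale(baseline, control, future)
  expect_lt(max(abs(out$layers$t_08$values - 11)), 1e-9)
  expect_lt(max(abs(out$layers$p_08$values - 90)), 1e-9)

  # grid mismatch between control and future is an error
  other_g <- grid_spec(0, 80, 20, -20, 4, 4)
  expect_error(change_factor_downscale(baseline, control,
                                       constant_clim(other_g)), "grid")
})

test_that("the precipitation ratio is floored and capped", {
  fine_g <- grid_spec(0, 40, 10, -10, 4, 4)
  coarse_g <- grid_spec(0, 40, 20, -20, 2, 2)
  baseline <- constant_clim(fine_g, t = 5, p = 10)
  control <- constant_clim(coarse_g, t = 5, p = 0)    # dry control cell
  future <- constant_clim(coarse_g, t = 5, p = 50)
  out <- change_factor_downscale(baseline, control, future,
                                 eps_mm = 0.1, ratio_cap = 10)
  # ratio = min(50 / max(0, 0.1), 10) = 10 everywhere
  expect_true(all(out$layers$p_06$values == 100))
})

test_that("downscaling conserves coarse block means when baseline matches control", {
  coarse_g <- grid_spec(0, 120, 40, -40, 3, 3)
  set.seed(63)
  control_layers <- list(); future_layers <- list()
  for (m in 1:12) {
    tn <- sprintf("t_%02d", m); pn <- sprintf("p_%02d", m)
    control_layers[[tn]] <- make_raster(coarse_g, matrix(stats::rnorm(9, 10), 3))
    control_layers[[pn]] <- make_raster(coarse_g,
                                        matrix(stats::runif(9, 20, 80), 3))
    future_layers[[tn]] <- make_raster(coarse_g,
                                       control_layers[[tn]]$values + 2)
    future_layers[[pn]] <- make_raster(coarse_g,
                                       control_layers[[pn]]$values * 1.2)
  }
  control <- raster_stack(control_layers)
  future <- raster_stack(future_layers)
  baseline_layers <- lapply(control$layers, function(l) block_expand(l, 4))
  baseline <- raster_stack(baseline_layers)
  out <- change_factor_downscale(baseline, control, future)
  # interior coarse block: block-mean of downscaled future == coarse future
  bm <- block_mean(out$layers$t_03, 4)
  expect_lt(abs(bm$values[2, 2] - future$layers$t_03$values[2, 2]), 1e-6)
  bmp <- block_mean(out$layers$p_03, 4)
  expect_lt(abs(bmp$values[2, 2] - future$layers$p_03$values[2, 2]), 1e-6)
})

test_that("climatic ensemble mean averages members and propagates nodata", {
  g <- tiny_grid(2, 2)
  s0 <- constant_clim(g, t = 0, p = 10)
  s2 <- constant_clim(g, t = 2, p = 30)
  m <- ensemble_mean_climate(list(s0, s2))
  expect_true(all(m$layers$t_01$values == 1))
  expect_true(all(m$layers$p_01$values == 20))
  expect_equal(ensemble_mean_climate(list(s2))$layers$t_05$values,
               s2$layers$t_05$values)
  expect_error(ensemble_mean_climate(list()), "empty")

  # 11 seeded members against a brute-force summation oracle
  set.seed(64)
  members <- lapply(1:11, function(i) {
    st <- constant_clim(g)
    st$layers$t_01 <- make_raster(g, matrix(stats::rnorm(4), 2, 2))
    st
  })
  got <- ensemble_mean_climate(members)$layers$t_01$values
  want <- matrix(0, 2, 2)
  for (s in members) want <- want + s$layers$t_01$values
  expect_lt(max(abs(got - want / 11)), 1e-12)

  # nodata in any member poisons the mean
  members[[3]]$layers$t_01$values[1, 1] <- NA
  expect_true(is.na(ensemble_mean_climate(members)$layers$t_01$values[1, 1]))
})
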