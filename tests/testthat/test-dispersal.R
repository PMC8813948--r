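test_that("mean dispersal distance formula and monotonicity", {
  expect_equal(mean_from_mdd(10^0.795), 1)
  expect_equal(mean_from_mdd(1000), 10^((3 - 0.795) / 0.984))
  mdds <- 10^seq(0.5, 4, length.out = 50)
  expect_true(all(diff(mean_from_mdd(mdds)) > 0))
  expect_true(all(mean_from_mdd(mdds[mdds > 10]) <= mdds[mdds > 10]))
  expect_error(mean_from_mdd(0), "positive")
})

test_that("trait-based MDD prediction: linearity, syndromes, override", {
  coeffs <- default_mdd_coeffs()
  coeffs$slope_log10_seed_mass <- 0
  coeffs$slope_log10_height <- 0
  coeffs$slope_terminal_velocity <- 0
  coeffs$intercept <- 2
  tr <- list(species_id = "x", dispersal_syndrome = "animal",
             seed_mass_mg = 50, plant_height_m = 20)
  expect_equal(predict_mdd(tr, coeffs), 100)

  # doubling seed mass moves log10 MDD by slope * log10(2)
  coeffs$slope_log10_seed_mass <- 0.4
  m1 <- predict_mdd(tr, coeffs)
  tr2 <- tr; tr2$seed_mass_mg <- 100
  expect_equal(log10(predict_mdd(tr2, coeffs)) - log10(m1), 0.4 * log10(2))

  # an expert override wins regardless of traits
  tr3 <- tr; tr3$mdd_override_m <- 500
  expect_equal(predict_mdd(tr3, coeffs), 500)

  # a missing required trait is a configuration error naming the trait
  tr4 <- list(species_id = "y", dispersal_syndrome = "wind",
              seed_mass_mg = 5, plant_height_m = NA)
  expect_error(predict_mdd(tr4), "plant_height_m")
})

test_that("the colonization kernel is exponential with a hard cutoff", {
  p <- dispersal_params(mdd = 1000)
  expect_equal(colonization_probability(0, p), 1)
  expect_equal(colonization_probability(p$mean_dist, p), exp(-1))
  expect_equal(colonization_probability(1001, p), 0)
  expect_gt(colonization_probability(1000, p), 0)
})

test_that("extinction empties unsuitable cells; no suitable cells, no occupancy", {
  g <- tiny_grid(4, 4, cell = 100)
  occ <- make_raster(g, matrix(1, 4, 4))
  none <- make_raster(g, matrix(0, 4, 4))
  out <- dispersal_step(occ, none, dispersal_params(mdd = 300), seed = 1)
  expect_true(all(out$values == 0))
})

test_that("a saturating kernel reproduces breadth-first reachable growth", {
  # mean_dist >> mdd makes every within-range colonization certain, so one
  # step must equal one ring of constrained BFS over suitable cells
  set.seed(91)
  g <- grid_spec(0, 10 * 100, 100, -100, 10, 10)
  suit_m <- matrix(stats::rbinom(100, 1, 0.7), 10, 10)
  occ_m <- matrix(0, 10, 10); occ_m[5, 5] <- 1
  suit_m[5, 5] <- 1
  p <- dispersal_params(mdd = 150, mean_dist = Inf)
  got <- dispersal_step(make_raster(g, occ_m), make_raster(g, suit_m), p,
                        seed = 92)
  # oracle: all suitable cells within 150 m of a suitable occupied source
  want <- occ_m * suit_m
  for (i in 1:10) for (j in 1:10) {
    if (suit_m[i, j] == 1 && occ_m[i, j] == 0) {
      for (si in 1:10) for (sj in 1:10) {
        if (occ_m[si, sj] == 1 && suit_m[si, sj] == 1 &&
            sqrt((i - si)^2 + (j - sj)^2) * 100 <= 150) {
          want[i, j] <- 1
        }
      }
    }
  }
  expect_identical(got$values, want)
})

test_that("single-source colonization frequency matches the closed form", {
  g <- grid_spec(0, 100, 100, -100, 3, 1)
  occ <- make_raster(g, matrix(c(1, 0, 0), 1, 3))
  suit <- make_raster(g, matrix(c(1, 0, 1), 1, 3))   # sink at 200 m
  p <- dispersal_params(mdd = 300)
  pd <- colonization_probability(200, p)
  set.seed(93)
  hits <- 0
  n_rep <- 4000
  for (i in seq_len(n_rep)) {
    hits <- hits + dispersal_step(occ, suit, p)$values[1, 3]
  }
  se <- sqrt(pd * (1 - pd) / n_rep)
  expect_lt(abs(hits / n_rep - pd), 3 * se)
})

test_that("replicate simulation classifies range change as documented", {
  g <- grid_spec(0, 6 * 100, 100, -100, 6, 6)
  init <- make_raster(g, matrix(0, 6, 6)); init$values[3, 2] <- 1
  p <- dispersal_params(mdd = 150, mean_dist = Inf, n_replicates = 5)

  # closed system: suitability fixed at the initial range
  suit0 <- make_raster(g, init$values)
  out0 <- run_dispersal(init, list(suit0), p, seed = 94)
  expect_identical(out0$category$values[3, 2], 1)
  expect_equal(out0$occupancy_freq$values[3, 2], 1)
  expect_true(all(out0$category$values[init$values == 0] == 0))

  # a front shifting beyond reach: old range decolonized, new range empty
  suit_far <- make_raster(g, matrix(0, 6, 6)); suit_far$values[3, 6] <- 1
  out1 <- run_dispersal(init, list(suit_far), p, seed = 95)
  expect_identical(out1$category$values[3, 2], 2)     # decolonized
  expect_identical(out1$category$values[3, 6], 4)     # suitable, unreachable
  expect_equal(out1$occupancy_freq$values[3, 6], 0)

  # an island beyond mdd stays unoccupied in every replicate
  suit_isl <- make_raster(g, init$values)
  suit_isl$values[6, 6] <- 1
  out2 <- run_dispersal(init, list(suit_isl), p, seed = 96)
  expect_equal(out2$occupancy_freq$values[6, 6], 0)
  expect_identical(out2$category$values[6, 6], 4)
})

test_that("occupancy stays within suitability and categories partition cells", {
  set.seed(97)
  g <- grid_spec(0, 12 * 100, 100, -100, 12, 12)
  init <- make_raster(g, matrix(stats::rbinom(144, 1, 0.2), 12, 12))
  series <- lapply(1:3, function(i)
    make_raster(g, matrix(stats::rbinom(144, 1, 0.5), 12, 12)))
  p <- dispersal_params(mdd = 250, n_replicates = 8)
  out <- run_dispersal(init, series, p, seed = 98)
  final_suit <- series[[3]]$values
  expect_true(all(out$occupied_majority$values[final_suit == 0] == 0))
  expect_true(all(out$category$values %in% 0:4))
  # recomputing categories from stored start/end/suitability reproduces them
  occ0 <- init$values; occ1 <- out$occupied_majority$values
  want <- matrix(0, 12, 12)
  want[occ0 == 1 & final_suit == 0] <- 2
  want[final_suit == 1 & occ1 == 1 & occ0 == 1] <- 1
  want[final_suit == 1 & occ1 == 1 & occ0 == 0] <- 3
  want[final_suit == 1 & occ1 == 0] <- 4
  expect_identical(out$category$values, want)
})

test_that("expected occupancy is non-decreasing in mean dispersal distance", {
  set.seed(99)
  g <- grid_spec(0, 15 * 100, 100, -100, 15, 15)
  init <- make_raster(g, matrix(0, 15, 15)); init$values[8, 2] <- 1
  suit <- make_raster(g, matrix(1, 15, 15))
  occ_at <- function(mean_dist) {
    p <- dispersal_params(mdd = 400, mean_dist = mean_dist,
                          n_replicates = 30)
    out <- run_dispersal(init, list(suit, suit), p, seed = 100)
    sum(out$occupancy_freq$values)
  }
  o <- vapply(c(50, 150, 400), occ_at, numeric(1))
  expect_true(all(diff(o) > -1e-9))
})
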