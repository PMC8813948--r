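#' @title Trait-based dispersal kernels and cellular-automaton simulation
#' @description Converts species traits to maximum dispersal distances,
#'   maximum to mean kernel distances, and simulates colonization of newly
#'   suitable habitat in 30-year steps with a negative-exponential kernel,
#'   local extinction on suitability loss, and replicate averaging.
#' @name dispersal
NULL

#' Mean dispersal distance from maximum dispersal distance
#'
#' `mean = 10^((log10(mdd) - 0.795) / 0.984)` (metres) — the log-log
#' regression linking maximum and mean dispersal distances across plant
#' dispersal studies. Strictly increasing; mean <= mdd for mdd above ~1 m.
#'
#' @param mdd Maximum dispersal distance in metres (> 0).
#' @return Mean dispersal distance in metres.
#' @export
mean_from_mdd <- function(mdd) {
  if (any(mdd <= 0)) stop("mean_from_mdd: mdd must be positive")
  10^((log10(mdd) - 0.795) / 0.984)
}

#' Default trait-to-MDD coefficient table
#'
#' Editable log-log linear form: `log10(MDD) = intercept(syndrome) +
#' s_mass * log10(seed mass) + s_height * log10(height) + s_tv * terminal
#' velocity`. The shipped values are documented placeholders of the right
#' order for trees (wind > animal > unassisted); they are configuration, not
#' a re-estimated model.
#'
#' @return Data frame with one row per dispersal syndrome.
#' @export
default_mdd_coeffs <- function() {
  data.frame(
    syndrome = c("wind", "animal", "none"),
    intercept = c(2.2, 2.5, 1.4),
    slope_log10_seed_mass = c(-0.1, 0.1, -0.1),
    slope_log10_height = c(0.9, 0.4, 0.6),
    slope_terminal_velocity = c(-0.3, 0, 0),
    stringsAsFactors = FALSE)
}

#' Predict maximum dispersal distance from traits
#'
#' Applies the syndrome-specific log-log linear form; a non-NA
#' `mdd_override_m` in the trait row takes precedence (the expert-knowledge
#' case). Terminal velocity enters untransformed and only where the
#' coefficient is nonzero; it is required then (wind-dispersed species).
#'
#' @param traits One-row data frame (or list) with `dispersal_syndrome`,
#'   `seed_mass_mg`, `plant_height_m`, optionally `terminal_velocity_ms`
#'   and `mdd_override_m`.
#' @param coeffs Coefficient table as [default_mdd_coeffs()].
#' @return MDD in metres.
#' @export
predict_mdd <- function(traits, coeffs = default_mdd_coeffs()) {
  traits <- as.list(traits)
  ov <- traits$mdd_override_m
  if (!is.null(ov) && length(ov) == 1 && !is.na(ov)) return(as.numeric(ov))
  cs <- coeffs[coeffs$syndrome == traits$dispersal_syndrome, ]
  if (nrow(cs) != 1)
    stop("predict_mdd: no coefficients for syndrome '",
         traits$dispersal_syndrome, "'")
  for (tr in c("seed_mass_mg", "plant_height_m")) {
    if (is.null(traits[[tr]]) || is.na(traits[[tr]]))
      stop("predict_mdd: species '", traits$species_id %||% "?",
           "' lacks required trait '", tr, "' and has no MDD override")
  }
  lg <- cs$intercept +
    cs$slope_log10_seed_mass * log10(traits$seed_mass_mg) +
    cs$slope_log10_height * log10(traits$plant_height_m)
  if (cs$slope_terminal_velocity != 0) {
    tv <- traits$terminal_velocity_ms
    if (is.null(tv) || is.na(tv))
      stop("predict_mdd: species '", traits$species_id %||% "?",
           "' lacks required trait 'terminal_velocity_ms' and has no ",
           "MDD override")
    lg <- lg + cs$slope_terminal_velocity * tv
  }
  10^lg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Dispersal simulation parameters
#'
#' @param mdd Maximum dispersal distance (m).
#' @param mean_dist Mean kernel distance (m); derived from `mdd` by
#'   [mean_from_mdd()] when NULL.
#' @param maturity_steps Steps before a colonist emits propagules (fixed 1:
#'   a 30-year step covers maturation).
#' @param propagule_prob Propagule production probability (default 1).
#' @param step_years Years per dispersal step (default 30).
#' @param n_replicates Stochastic replicates to average (default 30).
#' @return List of class `dispersal_params`.
#' @export
dispersal_params <- function(mdd, mean_dist = NULL, maturity_steps = 1,
                             propagule_prob = 1, step_years = 30,
                             n_replicates = 30) {
  if (is.null(mean_dist)) mean_dist <- mean_from_mdd(mdd)
  stopifnot(mdd > 0, mean_dist > 0, propagule_prob >= 0, propagule_prob <= 1)
  structure(list(mdd = mdd, mean_dist = mean_dist,
                 maturity_steps = maturity_steps,
                 propagule_prob = propagule_prob, step_years = step_years,
                 n_replicates = n_replicates),
            class = "dispersal_params")
}

#' Colonization probability at distance
#'
#' Negative-exponential kernel with a hard cutoff at the maximum dispersal
#' distance: `p(d) = propagule_prob * exp(-d / mean_dist)` for `d <= mdd`,
#' 0 beyond.
#'
#' @param distance Distance(s) in metres (>= 0).
#' @param params A [dispersal_params()].
#' @return Probability vector.
#' @export
colonization_probability <- function(distance, params) {
  stopifnot(all(distance >= 0))
  p <- params$propagule_prob * exp(-distance / params$mean_dist)
  p[distance > params$mdd] <- 0
  p
}

# kernel offsets within mdd (centre-to-centre distances), excluding (0,0)
kernel_offsets <- function(grid, params) {
  cs <- abs(grid$cell_size_x)
  reach <- floor(params$mdd / cs)
  off <- expand.grid(dr = -reach:reach, dc = -reach:reach)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  d <- sqrt(off$dr^2 + off$dc^2) * cs
  keep <- d <= params$mdd
  off <- off[keep, , drop = FALSE]
  off$p <- colonization_probability(d[keep], params)
  off[off$p > 0, , drop = FALSE]
}

# shift matrix by (dr, dc), zero-filling exposed margins
shift_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  r0 <- max(1, 1 + dr); r1 <- min(nr, nr + dr)
  c0 <- max(1, 1 + dc); c1 <- min(nc, nc + dc)
  if (r0 > r1 || c0 > c1) return(out)
  out[r0:r1, c0:c1] <- m[(r0:r1) - dr, (c0:c1) - dc, drop = FALSE]
  out
}

#' One synchronous dispersal step
#'
#' Extinction first: occupied cells that lost suitability become empty.
#' Colonization: every unoccupied suitable sink is colonized with
#' probability `1 - prod_i (1 - p(d_i))` over all source cells within the
#' maximum dispersal distance, where sources are cells occupied *before*
#' the step and still suitable now (a dying cell emits no propagules).
#' Bernoulli draws are taken from the seeded stream in row-major sink
#' order, so runs are reproducible.
#'
#' @param occupied Binary `tr_raster` (pre-step occupancy).
#' @param suitable Binary `tr_raster` (this step's suitability).
#' @param params A [dispersal_params()].
#' @param seed Optional integer seed (NULL uses the current RNG stream).
#' @return Binary `tr_raster` of post-step occupancy.
#' @export
dispersal_step <- function(occupied, suitable, params, seed = NULL) {
  if (!grids_equal(occupied$grid, suitable$grid))
    stop("dispersal_step: occupancy and suitability grids differ")
  if (!is.null(seed)) set.seed(seed)
  g <- occupied$grid
  occ <- occupied$values
  occ[is.na(occ)] <- 0
  suit <- suitable$values
  suit[is.na(suit)] <- 0
  src <- occ * suit                       # survivors emit propagules
  new_occ <- src                          # extinction applied
  sinks <- which(t(suit == 1 & new_occ == 0))  # row-major order indices
  if (length(sinks)) {
    off <- kernel_offsets(g, params)
    log_acc <- matrix(0, g$n_rows, g$n_cols)
    certain <- matrix(FALSE, g$n_rows, g$n_cols)
    for (i in seq_len(nrow(off))) {
      s <- shift_matrix(src, off$dr[i], off$dc[i])
      if (off$p[i] >= 1) {
        certain <- certain | (s > 0)
      } else {
        log_acc <- log_acc + s * log1p(-off$p[i])
      }
    }
    p_col <- 1 - exp(log_acc)
    p_col[certain] <- 1
    p_col_t <- t(p_col)                   # row-major vectorization
    u <- stats::runif(length(sinks))
    hit <- sinks[u < p_col_t[sinks]]
    if (length(hit)) {
      tm <- t(new_occ)
      tm[hit] <- 1
      new_occ <- t(tm)
    }
  }
  make_raster(g, new_occ, nodata = 255)
}

#' Run the replicate dispersal simulation and classify range change
#'
#' Per replicate, one [dispersal_step()] is taken against each entry of the
#' suitability series in order (30-year steps); with maturity 1, cells
#' colonized at one step emit propagules from the next. The occupancy
#' frequency is the across-replicate mean of the final state; a cell counts
#' as occupied when the majority (frequency >= 0.5) of replicates reach it.
#'
#' Range-change categories (final suitability S, initial occupancy O0,
#' majority final occupancy O1): 0 absent (!O0, !S); 1 stable presence
#' (O0, S, O1); 2 decolonized (O0, !S); 3 colonized (!O0, S, O1);
#' 4 suitable but not occupied (S, !O1, reachable in no replicate majority).
#'
#' @param initial_occupied Binary `tr_raster` (current range).
#' @param suitability_series Ordered list of binary `tr_raster`s (e.g.
#'   2035, 2065, 2095).
#' @param params A [dispersal_params()].
#' @param seed Integer seed; replicate r uses stream `seed + r`.
#' @return List of class `dispersal_outcome`: `occupancy_freq` (raster in
#'   [0,1]), `occupied_majority` (binary), `category` (codes 0-4),
#'   `final_suitable`.
#' @export
run_dispersal <- function(initial_occupied, suitability_series, params,
                          seed = 1) {
  stopifnot(length(suitability_series) >= 1)
  g <- initial_occupied$grid
  acc <- matrix(0, g$n_rows, g$n_cols)
  for (r in seq_len(params$n_replicates)) {
    set.seed(seed + r)
    state <- initial_occupied
    for (suit in suitability_series) {
      state <- dispersal_step(state, suit, params, seed = NULL)
    }
    acc <- acc + state$values
  }
  freq <- acc / params$n_replicates
  occ1 <- (freq >= 0.5) + 0
  occ0 <- initial_occupied$values
  occ0[is.na(occ0)] <- 0
  suitN <- suitability_series[[length(suitability_series)]]$values
  suitN[is.na(suitN)] <- 0
  cat_m <- matrix(0, g$n_rows, g$n_cols)
  cat_m[occ0 == 1 & suitN == 0] <- 2                    # decolonized
  cat_m[suitN == 1 & occ1 == 1 & occ0 == 1] <- 1        # stable presence
  cat_m[suitN == 1 & occ1 == 1 & occ0 == 0] <- 3        # colonized
  cat_m[suitN == 1 & occ1 == 0] <- 4                    # suitable, empty
  structure(list(occupancy_freq = make_raster(g, freq),
                 occupied_majority = make_raster(g, occ1, nodata = 255),
                 category = make_raster(g, cat_m, nodata = 255),
                 final_suitable = make_raster(g, suitN, nodata = 255)),
            class = "dispersal_outcome")
}
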