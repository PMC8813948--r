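#' @title Ensemble assembly, evaluation and projection
#' @description Surface-range-envelope pseudo-absence design, true-skill-
#'   statistic evaluation and binarization, spatial block cross-validation,
#'   consensus averaging with a TSS retention floor, permutation variable
#'   importance, the multivariate environmental similarity surface, and the
#'   two future-projection modes (climatic ensemble mean vs SDM ensemble
#'   mean with a minimum-valid-members rule).
#' @name sdm-ensemble
NULL

#' Build a surface range envelope from presence predictor values
#'
#' Per climatic predictor the envelope spans the `q` to `1-q` empirical
#' quantiles of the presence values; a point is inside the envelope iff it
#' lies within the bounds on *all* predictors.
#'
#' @param presence_env Matrix/data frame of climatic predictor values at
#'   presences (>= 10 rows).
#' @param q Quantile level in [0, 0.5) (default 0.025; `q = 0` gives the
#'   min/max envelope).
#' @return Object of class `sre_envelope`: matrix with rows `lower`,`upper`.
#' @export
build_sre <- function(presence_env, q = 0.025) {
  presence_env <- as.matrix(presence_env)
  stopifnot(nrow(presence_env) >= 10)
  if (q < 0 || q >= 0.5) stop("build_sre: q must lie in [0, 0.5)")
  b <- apply(presence_env, 2, stats::quantile, probs = c(q, 1 - q),
             names = FALSE, type = 7)
  rownames(b) <- c("lower", "upper")
  structure(b, class = "sre_envelope")
}

#' Test points against a surface range envelope
#'
#' @param envelope An `sre_envelope`.
#' @param env Matrix/data frame containing the envelope's predictors.
#' @return Logical vector: TRUE inside (all predictors within bounds).
#' @export
sre_inside <- function(envelope, env) {
  env <- as.matrix(env)[, colnames(unclass(envelope)), drop = FALSE]
  b <- unclass(envelope)
  inside <- rep(TRUE, nrow(env))
  for (j in seq_len(ncol(env))) {
    inside <- inside & env[, j] >= b["lower", j] & env[, j] <= b["upper", j]
  }
  inside & stats::complete.cases(env)
}

#' Sample pseudo-absence cells outside the climatic envelope
#'
#' Candidate cells are all valid grid cells whose climatic predictor vector
#' falls outside the envelope; `n` of them are drawn uniformly without
#' replacement (all of them, with a reported shortfall, if fewer exist).
#' Returned coordinates are cell centres.
#'
#' @param env Predictor `tr_stack`.
#' @param envelope An `sre_envelope` built on the climatic predictors.
#' @param n Number of pseudo-absences (default 10000).
#' @param seed Integer seed.
#' @return Data frame (x, y) with attribute `shortfall` (0 when `n` drawn).
#' @export
sample_pseudoabsences <- function(env, envelope, n = 10000, seed = 1) {
  set.seed(seed)
  m <- stack_as_matrix(env)
  valid <- stats::complete.cases(m)
  inside <- sre_inside(envelope, m)
  cand <- which(valid & !inside)
  if (!length(cand))
    stop("sample_pseudoabsences: no cells outside the envelope")
  take <- min(n, length(cand))
  sel <- if (take == length(cand)) cand else sample(cand, take)
  g <- env$grid
  row <- (sel - 1) %/% g$n_cols + 1    # row-major cell order
  col <- (sel - 1) %% g$n_cols + 1
  cc <- cell_centres(g)
  out <- data.frame(x = cc$x[col], y = cc$y[row])
  attr(out, "shortfall") <- as.integer(n - take)
  out
}

# ---- TSS ----------------------------------------------------------------

#' True skill statistic at a threshold
#'
#' Predicted presence iff `score >= threshold`. Reports the confusion
#' counts, sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)` and
#' `tss = sensitivity + specificity - 1`.
#'
#' @param scores Integer scores 0-1000.
#' @param labels 0/1 observed labels (both classes must be present).
#' @param threshold Integer threshold.
#' @return List (tp, fp, fn, tn, sensitivity, specificity, tss, threshold).
#' @export
tss_at_threshold <- function(scores, labels, threshold) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("tss_at_threshold: both classes must be present")
  pred <- scores >= threshold
  tp <- sum(pred & labels == 1); fp <- sum(pred & labels == 0)
  fn <- sum(!pred & labels == 1); tn <- sum(!pred & labels == 0)
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  list(tp = tp, fp = fp, fn = fn, tn = tn, sensitivity = sens,
       specificity = spec, tss = sens + spec - 1,
       threshold = as.integer(threshold))
}

#' TSS-maximizing threshold
#'
#' Scans all integer thresholds 0..1000; ties break toward the smallest
#' threshold.
#'
#' @param scores Integer scores 0-1000.
#' @param labels 0/1 labels (both classes present).
#' @return Integer threshold.
#' @export
optimal_threshold <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2)
    stop("optimal_threshold: both classes must be present")
  np <- sum(labels == 1); na <- sum(labels == 0)
  # counts of scores == s per class, then suffix sums give tp/fp at each t
  tab_p <- tabulate(scores[labels == 1] + 1L, nbins = 1001L)
  tab_a <- tabulate(scores[labels == 0] + 1L, nbins = 1001L)
  tp <- rev(cumsum(rev(tab_p)))            # tp at threshold t = index-1
  fp <- rev(cumsum(rev(tab_a)))
  sens <- tp / np
  spec <- (na - fp) / na
  tss <- sens + spec - 1
  as.integer(which.max(tss) - 1L)          # which.max takes first tie
}

# ---- block cross-validation ---------------------------------------------

#' Spatial block cross-validation of the member families
#'
#' The plane is tiled into `block_size_m` squares anchored at `anchor`;
#' occupied blocks are assigned round-robin, in seeded random order, to `k`
#' folds. Per family, the model is refitted on k-1 folds and scored on the
#' held-out fold at the held-out TSS-maximizing threshold; fold TSS values
#' are averaged. Folds missing a class are skipped and counted.
#'
#' @param cal An `sdm_calibration` with coordinates.
#' @param block_size_m Block edge in map units.
#' @param k Number of folds (default 5).
#' @param seed Integer seed (block shuffling and refits).
#' @param families Families to evaluate (default all six).
#' @return Data frame: family, cv_tss (mean over used folds),
#'   n_folds_used, n_folds_skipped.
#' @export
block_cross_validate <- function(cal, block_size_m, k = 5, seed = 1,
                                 families = sdm_families(),
                                 anchor = c(0, 0)) {
  stopifnot(inherits(cal, "sdm_calibration"), !is.null(cal$xy))
  set.seed(seed)
  bx <- floor((cal$xy[, "x"] - anchor[1]) / block_size_m)
  by <- floor((cal$xy[, "y"] - anchor[2]) / block_size_m)
  block <- paste(bx, by, sep = "\r")
  blocks <- unique(block)
  if (length(blocks) < k)
    stop("block_cross_validate: only ", length(blocks),
         " occupied blocks for ", k, " folds")
  shuffled <- sample(blocks)
  fold_of_block <- stats::setNames(rep_len(seq_len(k), length(shuffled)),
                                   shuffled)
  fold <- fold_of_block[block]
  res <- list()
  for (fam in families) {
    tss_vals <- numeric(0); skipped <- 0L
    for (f in seq_len(k)) {
      tr <- which(fold != f); te <- which(fold == f)
      if (length(unique(cal$label[te])) < 2 ||
          length(unique(cal$label[tr])) < 2 || sum(cal$label[tr]) < 30) {
        skipped <- skipped + 1L
        next
      }
      mem <- tryCatch(
        fit_members(subset_calibration(cal, tr), families = fam,
                    seed = seed)[[fam]],
        error = function(e) NULL)
      if (is.null(mem) || !mem$ok) { skipped <- skipped + 1L; next }
      p <- predict_member(mem, cal$data[te, , drop = FALSE])
      scores <- as.integer(round(1000 * p))
      thr <- optimal_threshold(scores, cal$label[te])
      tss_vals <- c(tss_vals,
                    tss_at_threshold(scores, cal$label[te], thr)$tss)
    }
    res[[fam]] <- data.frame(family = fam,
                             cv_tss = if (length(tss_vals)) mean(tss_vals)
                                      else NA_real_,
                             n_folds_used = length(tss_vals),
                             n_folds_skipped = skipped)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Attach cross-validated TSS values to fitted members
#'
#' @param members List from [fit_members()].
#' @param cv Data frame from [block_cross_validate()].
#' @return The members with `cv_tss` filled in.
#' @export
set_member_tss <- function(members, cv) {
  for (i in seq_len(nrow(cv))) {
    fam <- cv$family[i]
    if (fam %in% names(members)) members[[fam]]$cv_tss <- cv$cv_tss[i]
  }
  members
}

# ---- consensus ----------------------------------------------------------

#' Consensus ensemble projection for the current period
#'
#' Members whose cross-validated TSS exceeds `tss_floor` are retained; the
#' consensus probability map is the re-rounded unweighted mean of their
#' integer (0-1000) projections. Per-cell member dispersion is the
#' coefficient of variation (sd/mean) across retained members (NA where the
#' mean is 0). The binary map thresholds the consensus at the
#' TSS-maximizing threshold computed on the calibration points.
#'
#' @param members Members with `cv_tss` set (see [set_member_tss()]).
#' @param env Current-period predictor `tr_stack`.
#' @param cal The `sdm_calibration` (supplies points for the threshold).
#' @param tss_floor Retention floor (default 0.7; retention is strict `>`).
#' @return List of class `ensemble_result`: `consensus_prob` (int raster),
#'   `member_dispersion`, `binary`, `tss_threshold`, `retained_members`,
#'   `member_maps`.
#' @export
consensus <- function(members, env, cal, tss_floor = 0.7) {
  usable <- Filter(function(m) m$ok && !is.na(m$cv_tss) &&
                     m$cv_tss > tss_floor, members)
  if (!length(usable))
    stop("consensus: no member exceeds the TSS floor (",
         tss_floor, "); species unmodellable")
  maps <- lapply(usable, function(m) predict_prob(m, env))
  arr <- simplify2array(lapply(maps, function(r) r$values))
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  mu <- apply(arr, c(1, 2), mean)
  sdv <- if (dim(arr)[3] > 1) apply(arr, c(1, 2), stats::sd) else
    matrix(0, nrow(mu), ncol(mu))
  cons <- make_raster(env$grid, round(mu), nodata = 255)
  cv <- sdv / mu
  cv[!is.na(mu) & mu == 0] <- NA
  disp <- make_raster(env$grid, cv)
  # threshold on calibration points, consensus scores
  pm <- vapply(usable, function(m) predict_member(m, cal$data),
               numeric(nrow(cal$data)))
  sc <- as.integer(round(1000 * rowMeans(pm)))
  thr <- optimal_threshold(sc, cal$label)
  bin <- make_raster(env$grid, (cons$values >= thr) + 0, nodata = 255)
  structure(list(consensus_prob = cons, member_dispersion = disp,
                 binary = bin, tss_threshold = thr,
                 retained_members = names(usable), member_maps = maps,
                 members = usable),
            class = "ensemble_result")
}

# ---- permutation importance ---------------------------------------------

#' Permutation variable importance
#'
#' For each predictor, the column is permuted, predictions recomputed, and
#' the Pearson correlation `r` between permuted and reference predictions
#' taken; the procedure is repeated `n_rep` times and importance reported as
#' `1 - mean(r)`. Constant reference predictions leave `r` undefined; such
#' predictors get importance 0 and a `flagged` mark.
#'
#' @param predict_fun Function mapping a predictor data frame to a numeric
#'   prediction vector (a member or a consensus closure).
#' @param sample_env Data frame of predictor samples (>= 50 rows).
#' @param n_rep Number of permutation repeats (default 10).
#' @param seed Integer seed.
#' @return Data frame: predictor, importance, flagged.
#' @export
variable_importance <- function(predict_fun, sample_env, n_rep = 10,
                                seed = 1) {
  sample_env <- as.data.frame(sample_env)
  stopifnot(nrow(sample_env) >= 50)
  set.seed(seed)
  ref <- predict_fun(sample_env)
  out <- data.frame(predictor = names(sample_env),
                    importance = NA_real_, flagged = FALSE)
  for (j in seq_along(sample_env)) {
    rs <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      perm <- sample_env
      perm[[j]] <- perm[[j]][sample.int(nrow(perm))]
      pp <- predict_fun(perm)
      rs[r] <- suppressWarnings(stats::cor(ref, pp))
    }
    if (all(is.na(rs))) {
      out$importance[j] <- 0
      out$flagged[j] <- TRUE
    } else {
      out$importance[j] <- 1 - mean(rs, na.rm = TRUE)
    }
  }
  out
}

#' Prediction closure for a consensus of members
#'
#' @param members List of usable `sdm_member`s.
#' @return Function data frame -> mean member probability.
#' @export
consensus_predict_fun <- function(members) {
  function(newdata) {
    pm <- vapply(members, function(m) predict_member(m, newdata),
                 numeric(nrow(as.data.frame(newdata))))
    rowMeans(pm)
  }
}

# ---- MESS ---------------------------------------------------------------

mess_similarity_one <- function(ref, probe) {
  ref <- ref[!is.na(ref)]
  n <- length(ref)
  mn <- min(ref); mx <- max(ref); rng <- mx - mn
  if (rng == 0) {
    return(ifelse(is.na(probe), NA_real_, ifelse(probe == mn, 100, 0)))
  }
  sr <- sort(ref)
  f <- 100 * findInterval(probe, sr, left.open = TRUE) / n  # % strictly below
  sim <- ifelse(f == 0, 100 * (probe - mn) / rng,
         ifelse(f <= 50, 2 * f,
         ifelse(f < 100, 2 * (100 - f),
                100 * (mx - probe) / rng)))
  sim[is.na(probe)] <- NA_real_
  sim
}

#' Multivariate environmental similarity surface
#'
#' Per cell and predictor with probe value `p`, let `f` be the percentage of
#' reference values strictly below `p`; similarity is
#' `100 (p - min)/(max - min)` if `f = 0`, `2 f` if `0 < f <= 50`,
#' `2 (100 - f)` if `50 < f < 100`, and `100 (max - p)/(max - min)` if
#' `f = 100`. The MESS value is the minimum over predictors; negative cells
#' are non-analog climate (extrapolation).
#'
#' @param reference_env Matrix/data frame of reference predictor values
#'   (>= 2 rows), typically calibration presences plus pseudo-absences.
#' @param projection Predictor `tr_stack` to probe.
#' @return A `tr_raster` of MESS values (min over predictors).
#' @export
mess <- function(reference_env, projection) {
  reference_env <- as.matrix(reference_env)
  stopifnot(nrow(reference_env) >= 2)
  vars <- colnames(reference_env)
  stopifnot(all(vars %in% stack_names(projection)))
  m <- stack_as_matrix(projection, vars)
  sims <- vapply(vars, function(v) mess_similarity_one(reference_env[, v],
                                                       m[, v]),
                 numeric(nrow(m)))
  mn <- apply(sims, 1, function(z) if (any(is.na(z))) NA_real_ else min(z))
  make_raster(projection$grid,
              matrix(mn, nrow = projection$grid$n_rows, byrow = TRUE))
}

# ---- future projection --------------------------------------------------

#' Project the consensus ensemble into future conditions
#'
#' Two modes mirror the published products: `climatic_ensemble` projects the
#' consensus once onto the ensemble-mean climate of the model runs;
#' `sdm_ensemble` projects it per run and then averages per cell, keeping a
#' cell only where at least `min_valid` of the runs are valid (the
#' "8 of 11" rule), and also reports the per-cell standard deviation.
#' Non-analog cells (MESS < 0 against `reference_env`) are set to NA per
#' run. Binary maps reuse the current-period TSS threshold unchanged.
#'
#' @param ens An `ensemble_result` from [consensus()].
#' @param future_envs List of future predictor `tr_stack`s (one per model
#'   run).
#' @param mode `"climatic_ensemble"` or `"sdm_ensemble"`.
#' @param min_valid Minimum valid runs per cell in `sdm_ensemble` mode
#'   (default 8).
#' @param reference_env Reference matrix for MESS (NULL disables masking).
#' @return List of class `ensemble_projection`: `prob` (int raster), `sd`
#'   (sdm_ensemble mode), `binary`, `n_valid`, `mode`, `tss_threshold`.
#' @export
project_future <- function(ens, future_envs, mode = c("climatic_ensemble",
                                                      "sdm_ensemble"),
                           min_valid = 8, reference_env = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(ens, "ensemble_result"), length(future_envs) >= 1)
  members <- ens$members
  g <- future_envs[[1]]$grid
  project_once <- function(env) {
    arr <- simplify2array(lapply(members,
                                 function(m) predict_prob(m, env)$values))
    if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
    mu <- round(apply(arr, c(1, 2), mean))
    if (!is.null(reference_env)) {
      ms <- mess(reference_env, env)
      mu[!is.na(ms$values) & ms$values < 0] <- NA
      mu[is.na(ms$values)] <- NA
    }
    mu
  }
  if (mode == "climatic_ensemble") {
    env_mean <- ensemble_mean_climate(future_envs)
    mu <- project_once(env_mean)
    prob <- make_raster(g, mu, nodata = 255)
    bin <- make_raster(g, (mu >= ens$tss_threshold) + 0, nodata = 255)
    return(structure(list(prob = prob, sd = NULL, binary = bin,
                          n_valid = NULL, mode = mode,
                          tss_threshold = ens$tss_threshold),
                     class = "ensemble_projection"))
  }
  if (length(future_envs) < min_valid)
    stop("project_future: fewer model runs (", length(future_envs),
         ") than min_valid (", min_valid, ")")
  maps <- lapply(future_envs, project_once)
  arr <- simplify2array(maps)
  nv <- apply(arr, c(1, 2), function(z) sum(!is.na(z)))
  mu <- apply(arr, c(1, 2), function(z) mean(z, na.rm = TRUE))
  sdv <- apply(arr, c(1, 2), function(z) stats::sd(z, na.rm = TRUE))
  bad <- nv < min_valid
  mu[bad] <- NA; sdv[bad] <- NA
  mu <- round(mu)
  prob <- make_raster(g, mu, nodata = 255)
  bin <- make_raster(g, (mu >= ens$tss_threshold) + 0, nodata = 255)
  structure(list(prob = prob, sd = make_raster(g, sdv), binary = bin,
                 n_valid = make_raster(g, nv), mode = mode,
                 tss_threshold = ens$tss_threshold),
            class = "ensemble_projection")
}
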