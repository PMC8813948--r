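#' @title SDM member model families
#' @description The six model families of the ensemble — GLM, GAM, gradient
#'   boosting, MARS, a MaxEnt-like penalized logistic model restricted to
#'   linear+quadratic features, and random forest — behind one common
#'   fit/predict interface with prevalence-0.5 case weighting.
#' @name sdm-members
NULL

#' The six ensemble family tags
#' @return Character vector.
#' @export
sdm_families <- function() c("glm", "gam", "gbm", "mars", "maxent", "rf")

#' Build a calibration set with prevalence-0.5 weighting
#'
#' Presences carry weight 1; pseudo-absences are down-weighted by
#' `n_presence / n_absence` so total presence and absence weight are equal
#' (prevalence 0.5), for every family that accepts case weights.
#'
#' @param presence_env Matrix/data frame of predictor values at presences.
#' @param absence_env Matrix/data frame at pseudo-absences (same columns).
#' @param presence_xy,absence_xy Optional 2-column coordinate matrices,
#'   needed for block cross-validation.
#' @return List of class `sdm_calibration`: `data` (predictors), `label`
#'   (1/0), `weights`, `xy`.
#' @export
make_calibration <- function(presence_env, absence_env,
                             presence_xy = NULL, absence_xy = NULL) {
  presence_env <- as.data.frame(presence_env)
  absence_env <- as.data.frame(absence_env)
  stopifnot(identical(names(presence_env), names(absence_env)))
  np <- nrow(presence_env); na <- nrow(absence_env)
  stopifnot(np > 0, na > 0)
  data <- rbind(presence_env, absence_env)
  ok <- stats::complete.cases(data)
  label <- c(rep(1L, np), rep(0L, na))
  w <- c(rep(1, np), rep(np / na, na))
  xy <- NULL
  if (!is.null(presence_xy) && !is.null(absence_xy)) {
    xy <- rbind(as.matrix(presence_xy), as.matrix(absence_xy))
    colnames(xy) <- c("x", "y")
    xy <- xy[ok, , drop = FALSE]
  }
  structure(list(data = data[ok, , drop = FALSE], label = label[ok],
                 weights = w[ok], xy = xy),
            class = "sdm_calibration")
}

subset_calibration <- function(cal, idx) {
  structure(list(data = cal$data[idx, , drop = FALSE],
                 label = cal$label[idx], weights = cal$weights[idx],
                 xy = if (is.null(cal$xy)) NULL else cal$xy[idx, , drop = FALSE]),
            class = "sdm_calibration")
}

# ---- family fitters ------------------------------------------------------

fit_family_glm <- function(cal) {
  vars <- names(cal$data)
  rhs <- paste(c(vars, sprintf("I(%s^2)", vars)), collapse = " + ")
  df <- cal$data; df$.y <- cal$label
  fit <- suppressWarnings(stats::glm(
    stats::as.formula(paste(".y ~", rhs)), family = stats::binomial(),
    data = df, weights = cal$weights))
  list(fit = fit)
}

fit_family_gam <- function(cal) {
  vars <- names(cal$data)
  k <- 4
  terms <- vapply(vars, function(v) {
    if (length(unique(cal$data[[v]])) > k + 1) sprintf("s(%s, k = %d)", v, k)
    else v
  }, character(1))
  df <- cal$data; df$.y <- cal$label
  fit <- suppressWarnings(mgcv::gam(
    stats::as.formula(paste(".y ~", paste(terms, collapse = " + "))),
    family = stats::binomial(), data = df, weights = cal$weights,
    method = "REML"))
  list(fit = fit)
}

fit_family_gbm <- function(cal, seed = 1) {
  # normalize weights to mean 1: the booster's hessian-based regularization
  # is not scale-free, and predictions must not depend on the weights' unit
  w <- cal$weights / mean(cal$weights)
  dm <- xgboost::xgb.DMatrix(as.matrix(cal$data), label = cal$label,
                             weight = w)
  fit <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", eta = 0.1, max_depth = 3,
                  subsample = 1, colsample_bytree = 1, nthread = 1,
                  seed = seed),
    data = dm, nrounds = 150, verbose = 0)
  list(fit = fit, feature_names = names(cal$data))
}

fit_family_maxent <- function(cal) {
  # linear + quadratic features only (no product/threshold/hinge), ridge
  # penalty; weighted logistic regression on these features is the
  # down-weighted-background approximation to maxent
  X <- as.matrix(cal$data)
  Xq <- cbind(X, X^2)
  colnames(Xq) <- c(colnames(X), paste0(colnames(X), "_sq"))
  ctr <- colMeans(Xq); scl <- apply(Xq, 2, stats::sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(Xq, 2, ctr), 2, scl, "/")
  fit <- glmnet::glmnet(Xs, cal$label, family = "binomial", alpha = 0,
                        lambda = 1e-3, weights = cal$weights,
                        standardize = FALSE)
  list(fit = fit, centre = ctr, scale = scl, vars = colnames(X))
}

fit_family_rf <- function(cal, seed = 1) {
  df <- cal$data
  df$.y <- factor(cal$label, levels = c(0, 1))
  fit <- ranger::ranger(.y ~ ., data = df, probability = TRUE,
                        num.trees = 500, case.weights = cal$weights,
                        seed = seed, num.threads = 1)
  list(fit = fit)
}

#' Fit the six member models
#'
#' Each family is fitted on the weighted calibration set; a family that
#' errors or fails to converge is flagged unusable and excluded downstream
#' while the run continues.
#'
#' @param cal An `sdm_calibration` (needs >= 30 presences).
#' @param families Subset of [sdm_families()] (default all six).
#' @param seed Integer seed (stochastic families: boosting, random forest).
#' @return Named list of `sdm_member` objects (fields: `family`, `ok`,
#'   `fit`, `cv_tss` — NA until cross-validated).
#' @export
fit_members <- function(cal, families = sdm_families(), seed = 1) {
  stopifnot(inherits(cal, "sdm_calibration"))
  if (sum(cal$label == 1) < 30)
    stop("fit_members: need at least 30 presences")
  members <- list()
  for (fam in families) {
    m <- tryCatch({
      fitted <- switch(fam,
        glm = fit_family_glm(cal),
        gam = fit_family_gam(cal),
        gbm = fit_family_gbm(cal, seed),
        mars = fit_family_mars(cal),
        maxent = fit_family_maxent(cal),
        rf = fit_family_rf(cal, seed),
        stop("unknown family: ", fam))
      structure(c(list(family = fam, ok = TRUE, cv_tss = NA_real_,
                       predictors = names(cal$data)), fitted),
                class = "sdm_member")
    }, error = function(e) {
      warning("member '", fam, "' failed to fit: ", conditionMessage(e))
      structure(list(family = fam, ok = FALSE, cv_tss = NA_real_,
                     predictors = names(cal$data)),
                class = "sdm_member")
    })
    members[[fam]] <- m
  }
  members
}

#' Predict suitability from one member
#'
#' @param member An `sdm_member`.
#' @param newdata Matrix or data frame with the member's predictor columns.
#' @return Numeric vector of probabilities in [0, 1]; NA rows propagate NA.
#' @export
predict_member <- function(member, newdata) {
  stopifnot(inherits(member, "sdm_member"))
  if (!member$ok) stop("member '", member$family, "' is unusable")
  newdata <- as.data.frame(newdata)[, member$predictors, drop = FALSE]
  ok <- stats::complete.cases(newdata)
  p <- rep(NA_real_, nrow(newdata))
  if (!any(ok)) return(p)
  nd <- newdata[ok, , drop = FALSE]
  p[ok] <- switch(member$family,
    glm = stats::predict(member$fit, newdata = nd, type = "response"),
    gam = as.numeric(stats::predict(member$fit, newdata = nd,
                                    type = "response")),
    gbm = {
      dm <- xgboost::xgb.DMatrix(as.matrix(nd))
      stats::predict(member$fit, dm)
    },
    mars = predict_mars_fit(member, nd),
    maxent = {
      X <- as.matrix(nd)
      Xq <- cbind(X, X^2)
      Xs <- sweep(sweep(Xq, 2, member$centre), 2, member$scale, "/")
      as.numeric(stats::predict(member$fit, Xs, type = "response"))
    },
    rf = stats::predict(member$fit, data = nd,
                        num.threads = 1)$predictions[, "1"])
  pmin(pmax(p, 0), 1)
}

#' Project a member onto a predictor stack as integer probabilities
#'
#' Probabilities are stored, as in the published maps, as integers 0-1000:
#' `round(1000 p)`. NA cells propagate.
#'
#' @param member An `sdm_member`.
#' @param env Predictor `tr_stack`.
#' @return Integer-valued `tr_raster` (nodata 255 convention on disk).
#' @export
predict_prob <- function(member, env) {
  m <- stack_as_matrix(env, member$predictors)
  p <- predict_member(member, m)
  v <- matrix(round(1000 * p), nrow = env$grid$n_rows, byrow = TRUE)
  make_raster(env$grid, v, nodata = 255)
}

# ---- compact additive MARS ----------------------------------------------

mars_basis <- function(x, terms) {
  B <- matrix(1, nrow = length(x[[1]]), ncol = 1)
  for (tm in terms) {
    v <- x[[tm$var]]
    B <- cbind(B, pmax(v - tm$knot, 0), pmax(tm$knot - v, 0))
  }
  B
}

fit_family_mars <- function(cal, max_pairs = 10, n_knots = 11, penalty = 3) {
  X <- cal$data
  y <- cal$label
  w <- cal$weights
  n <- length(y)
  # candidate knots at interior quantiles per predictor
  cand <- list()
  for (v in names(X)) {
    qs <- unique(stats::quantile(X[[v]], probs = seq(0.08, 0.92,
                                                     length.out = n_knots),
                                 names = FALSE, type = 7))
    for (t in qs) cand[[length(cand) + 1]] <- list(var = v, knot = t)
  }
  wls_rss <- function(B) {
    fit <- stats::lm.wfit(B, y, w)
    sum(w * fit$residuals^2)
  }
  terms <- list()
  B <- matrix(1, n, 1)
  rss <- wls_rss(B)
  # forward pass: greedily add the hinge pair that most reduces weighted RSS
  for (step in seq_len(max_pairs)) {
    best <- NULL; best_rss <- rss
    for (cd in cand) {
      v <- X[[cd$var]]
      Bc <- cbind(B, pmax(v - cd$knot, 0), pmax(cd$knot - v, 0))
      r <- tryCatch(wls_rss(Bc), error = function(e) Inf)
      if (r < best_rss - 1e-12) { best <- cd; best_rss <- r }
    }
    if (is.null(best)) break
    terms[[length(terms) + 1]] <- best
    B <- cbind(B, pmax(X[[best$var]] - best$knot, 0),
               pmax(best$knot - X[[best$var]], 0))
    rss <- best_rss
    if (rss / sum(w) < 1e-8) break
  }
  # backward prune by GCV (effective parameters: columns + penalty per knot)
  gcv <- function(B, n_terms) {
    ep <- ncol(B) + penalty * n_terms
    if (ep >= n) return(Inf)
    wls_rss(B) / (n * (1 - ep / n)^2)
  }
  repeat {
    if (!length(terms)) break
    g0 <- gcv(mars_basis(X, terms), length(terms))
    scores <- vapply(seq_along(terms), function(j)
      gcv(mars_basis(X, terms[-j]), length(terms) - 1), numeric(1))
    j <- which.min(scores)
    if (scores[j] < g0) terms <- terms[-j] else break
  }
  # final weighted binomial refit on the selected basis
  B <- mars_basis(X, terms)
  df <- as.data.frame(B[, -1, drop = FALSE])
  if (ncol(df)) names(df) <- paste0("b", seq_len(ncol(df)))
  df$.y <- y
  refit <- suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(),
                                       data = df, weights = w))
  list(fit = refit, mars_terms = terms)
}

predict_mars_fit <- function(member, nd) {
  B <- mars_basis(nd, member$mars_terms)
  df <- as.data.frame(B[, -1, drop = FALSE])
  if (ncol(df)) names(df) <- paste0("b", seq_len(ncol(df)))
  as.numeric(stats::predict(member$fit, newdata = df, type = "response"))
}
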