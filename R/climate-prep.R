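#' @title Bioclimatic predictors and change-factor downscaling
#' @description Derivation of the retained predictor set from monthly
#'   climatologies, stepwise variance-inflation-factor screening, the
#'   change-factor (delta) downscaling of coarse climate-model anomalies
#'   onto a fine baseline, and the climatic ensemble mean.
#' @name climate-prep
NULL

month_layer_names <- function() {
  c(sprintf("t_%02d", 1:12), sprintf("p_%02d", 1:12))
}

check_monthly <- function(clim) {
  miss <- setdiff(month_layer_names(), stack_names(clim))
  if (length(miss))
    stop("monthly climatology is missing layers: ",
         paste(miss, collapse = ", "))
  invisible(clim)
}

#' Derive the bioclimatic predictor layers
#'
#' From 12 monthly temperature and precipitation layers computes, for the
#' northern hemisphere:
#' * `Mat` — mean annual temperature (deg C), mean of the 12 monthly means;
#' * `Ts`  — summer (JJA) mean temperature (deg C);
#' * `Pw`  — winter (DJF) mean precipitation (mm/month);
#' * `Ps`  — summer (JJA) mean precipitation (mm/month);
#' * `Ptot` — total annual precipitation (mm/year), sum of the 12 months;
#' * `Pse` — precipitation seasonality, sd/mean of the 12 monthly values
#'   with the mean floored at 1 mm to keep arid cells finite;
#' * `Ci`  — continentality (deg C), warmest minus coldest monthly mean.
#'
#' Soil layers (`pH`, `occ`) present in the input stack are passed through,
#' completing the 9-predictor set.
#'
#' @param clim `tr_stack` with `t_01..t_12`, `p_01..p_12` and optionally
#'   `pH`, `occ`.
#' @return A `tr_stack` of predictors.
#' @export
derive_bioclim <- function(clim) {
  check_monthly(clim)
  g <- clim$grid
  tm <- lapply(sprintf("t_%02d", 1:12), function(n) clim$layers[[n]]$values)
  pm <- lapply(sprintf("p_%02d", 1:12), function(n) clim$layers[[n]]$values)
  tarr <- simplify2array(tm)                 # rows x cols x 12
  parr <- simplify2array(pm)
  mat <- apply(tarr, c(1, 2), mean)
  ts <- (tm[[6]] + tm[[7]] + tm[[8]]) / 3
  pw <- (pm[[12]] + pm[[1]] + pm[[2]]) / 3
  ps <- (pm[[6]] + pm[[7]] + pm[[8]]) / 3
  ptot <- apply(parr, c(1, 2), sum)
  pmean <- ptot / 12
  psd <- apply(parr, c(1, 2), stats::sd)
  pse <- psd / pmax(pmean, 1)
  ci <- apply(tarr, c(1, 2), max) - apply(tarr, c(1, 2), min)
  layers <- list(Mat = make_raster(g, mat), Ts = make_raster(g, ts),
                 Ps = make_raster(g, ps), Pw = make_raster(g, pw),
                 Ptot = make_raster(g, ptot), Pse = make_raster(g, pse),
                 Ci = make_raster(g, ci))
  for (soil in c("pH", "occ")) {
    if (soil %in% stack_names(clim)) layers[[soil]] <- clim$layers[[soil]]
  }
  raster_stack(layers)
}

#' The climatic predictor names (soil excluded)
#' @return Character vector.
#' @export
climatic_predictors <- function() c("Mat", "Ts", "Ps", "Pw", "Ptot", "Pse", "Ci")

#' Stepwise variance-inflation-factor screening
#'
#' Iteratively drops the column with the largest VIF (computed as
#' 1/(1-R^2) of the OLS regression of that column on all others) until every
#' VIF is below `threshold`. On ties — notably perfectly collinear pairs,
#' where both VIFs are infinite — the later-listed column is dropped first.
#' Survivors are returned in input order. The screen is invariant to affine
#' rescaling of any column.
#'
#' @param x Numeric matrix or data frame of predictor samples (rows =
#'   points), e.g. predictor values at presences plus background.
#' @param threshold VIF threshold (default 10).
#' @return Character vector of retained column names.
#' @export
vif_screen <- function(x, threshold = 10) {
  x <- as.matrix(x)
  stopifnot(ncol(x) >= 2, !is.null(colnames(x)))
  keep <- colnames(x)
  vif_one <- function(j, cols) {
    yv <- x[, cols[j]]
    X <- x[, cols[-j], drop = FALSE]
    fit <- stats::lm.fit(cbind(1, X), yv)
    r2 <- 1 - sum(fit$residuals^2) / sum((yv - mean(yv))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  repeat {
    if (length(keep) < 2) break
    vifs <- vapply(seq_along(keep), vif_one, numeric(1), cols = keep)
    worst <- max(vifs)
    if (worst < threshold) break
    drop_idx <- max(which(vifs == worst))    # later-listed drops first on ties
    keep <- keep[-drop_idx]
  }
  intersect(colnames(x), keep)
}

#' Change-factor (delta) downscaling of one climate-model run
#'
#' Computes monthly anomalies on the coarse model grid — additive for
#' temperature (`future - control`) and multiplicative for precipitation
#' (`future / max(control, eps_mm)`, capped at `ratio_cap`) — regrids them
#' to the fine baseline grid by bilinear interpolation, and applies them to
#' the baseline climatology. Precipitation is clamped at zero.
#'
#' @param baseline_fine Fine-grid monthly `tr_stack` (the observed baseline).
#' @param control_coarse,future_coarse Coarse monthly `tr_stack`s on one grid.
#' @param eps_mm Floor for control precipitation in the ratio (default 0.1).
#' @param ratio_cap Maximum precipitation ratio (default 10).
#' @return Fine-grid future monthly `tr_stack`.
#' @export
change_factor_downscale <- function(baseline_fine, control_coarse,
                                    future_coarse, eps_mm = 0.1,
                                    ratio_cap = 10) {
  check_monthly(baseline_fine); check_monthly(control_coarse)
  check_monthly(future_coarse)
  if (!grids_equal(control_coarse$grid, future_coarse$grid))
    stop("control and future stacks must share one coarse grid")
  fg <- baseline_fine$grid
  cg <- control_coarse$grid
  out <- list()
  for (m in 1:12) {
    tn <- sprintf("t_%02d", m); pn <- sprintf("p_%02d", m)
    dT <- make_raster(cg, future_coarse$layers[[tn]]$values -
                        control_coarse$layers[[tn]]$values)
    ctrl_p <- pmax(control_coarse$layers[[pn]]$values, eps_mm)
    rP <- make_raster(cg, pmin(future_coarse$layers[[pn]]$values / ctrl_p,
                               ratio_cap))
    dT_fine <- bilinear_regrid(dT, fg)
    rP_fine <- bilinear_regrid(rP, fg)
    out[[tn]] <- make_raster(fg, baseline_fine$layers[[tn]]$values +
                               dT_fine$values)
    out[[pn]] <- make_raster(fg, pmax(baseline_fine$layers[[pn]]$values *
                                        rP_fine$values, 0))
  }
  for (soil in c("pH", "occ")) {
    if (soil %in% stack_names(baseline_fine))
      out[[soil]] <- baseline_fine$layers[[soil]]
  }
  raster_stack(out)
}

#' Per-cell ensemble mean of monthly climatologies
#'
#' Arithmetic mean over ensemble members, per layer and cell; a cell is NA
#' if any member is NA there.
#'
#' @param stacks Non-empty list of `tr_stack`s sharing a grid and layer set.
#' @return A `tr_stack` of means.
#' @export
ensemble_mean_climate <- function(stacks) {
  if (length(stacks) < 1) stop("ensemble_mean_climate: empty ensemble")
  nms <- stack_names(stacks[[1]])
  g <- stacks[[1]]$grid
  out <- list()
  for (nm in nms) {
    acc <- stacks[[1]]$layers[[nm]]$values
    if (length(stacks) > 1) {
      for (k in 2:length(stacks)) acc <- acc + stacks[[k]]$layers[[nm]]$values
    }
    out[[nm]] <- make_raster(g, acc / length(stacks))
  }
  raster_stack(out)
}
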