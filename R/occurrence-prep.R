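#' @title Occurrence cleaning, trimming, thinning and filtering
#' @description The occurrence-preparation chain applied before model
#'   calibration: per-cell deduplication on the fine analysis grid,
#'   native-range trimming, random one-per-block spatial thinning to remove
#'   uneven sampling effort, and a minimum-records filter.
#' @name occurrence-prep
NULL

check_occ <- function(occ) {
  stopifnot(is.data.frame(occ),
            all(c("species_id", "x", "y") %in% names(occ)))
  if (!("source_tag" %in% names(occ))) occ$source_tag <- NA_character_
  occ
}

#' Remove duplicate records per species per fine-grid cell
#'
#' At most one record per (species, cell) survives; the first record in
#' stable input order is kept. Records outside the grid are dropped and
#' counted in the `dropped_outside` attribute.
#'
#' @param occ Occurrence data frame (species_id, x, y, ...).
#' @param grid The fine analysis [grid_spec()].
#' @return Deduplicated data frame with attribute `dropped_outside`.
#' @export
dedupe_per_cell <- function(occ, grid) {
  occ <- check_occ(occ)
  if (nrow(occ) == 0) {
    attr(occ, "dropped_outside") <- 0L
    return(occ)
  }
  idx <- cell_index(grid, occ$x, occ$y)
  n_out <- sum(!idx$inside)
  occ <- occ[idx$inside, , drop = FALSE]
  idx <- idx[idx$inside, , drop = FALSE]
  key <- paste(occ$species_id, idx$row, idx$col, sep = "\r")
  keep <- !duplicated(key)
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_outside") <- as.integer(n_out)
  out
}

#' Trim occurrences to species' native ranges
#'
#' Records falling in mask-0 (or nodata) cells are removed. Species listed
#' in `keep_all` bypass the mask entirely (the naturalized-alien case where
#' the whole record set is trusted).
#'
#' @param occ Occurrence data frame.
#' @param masks Named list of binary `tr_raster` masks, one per species.
#' @param keep_all Character vector of species ids exempt from trimming.
#' @return Trimmed data frame.
#' @export
trim_to_native_range <- function(occ, masks, keep_all = character(0)) {
  occ <- check_occ(occ)
  if (nrow(occ) == 0) return(occ)
  sp <- unique(occ$species_id)
  missing <- setdiff(sp, c(names(masks), keep_all))
  if (length(missing))
    stop("no native-range mask and no keep-all flag for species: ",
         paste(missing, collapse = ", "))
  keep <- logical(nrow(occ))
  for (s in sp) {
    rows <- which(occ$species_id == s)
    if (s %in% keep_all) {
      keep[rows] <- TRUE
      next
    }
    m <- masks[[s]]
    idx <- cell_index(m$grid, occ$x[rows], occ$y[rows])
    v <- rep(NA_real_, length(rows))
    ok <- idx$inside
    v[ok] <- m$values[cbind(idx$row[ok], idx$col[ok])]
    keep[rows] <- !is.na(v) & v == 1
  }
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spatially thin occurrences to one record per block
#'
#' Per species, exactly one uniformly random record survives in every
#' occupied `block_size` x `block_size` block; the block lattice is anchored
#' at the grid origin. Deterministic per seed.
#'
#' @param occ Occurrence data frame.
#' @param grid Study [grid_spec()] (supplies the lattice anchor).
#' @param block_size Block edge in map units (default 40000, i.e. 40 km).
#' @param seed Integer seed.
#' @return Thinned data frame.
#' @export
thin_by_block <- function(occ, grid, block_size = 40000, seed = 1) {
  occ <- check_occ(occ)
  if (nrow(occ) == 0) return(occ)
  set.seed(seed)
  bx <- floor((occ$x - grid$origin_x) / block_size)
  by <- floor((occ$y - grid$origin_y) / block_size)
  key <- paste(occ$species_id, bx, by, sep = "\r")
  # one uniform pick per key, via a random priority per record
  pri <- stats::runif(nrow(occ))
  ord <- order(key, pri)
  keep_sorted <- !duplicated(key[ord])
  keep <- logical(nrow(occ))
  keep[ord] <- keep_sorted
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Drop species with too few occurrences
#'
#' Species with fewer than `min_n` records are removed entirely; the
#' boundary is inclusive (exactly `min_n` records is retained).
#'
#' @param occ Occurrence data frame.
#' @param min_n Minimum record count (default 30).
#' @return List with `occ` (filtered table) and `excluded` (character vector
#'   of dropped species ids).
#' @export
filter_min_occurrences <- function(occ, min_n = 30) {
  occ <- check_occ(occ)
  if (nrow(occ) == 0) return(list(occ = occ, excluded = character(0)))
  counts <- table(occ$species_id)
  excluded <- names(counts)[counts < min_n]
  out <- occ[!(occ$species_id %in% excluded), , drop = FALSE]
  rownames(out) <- NULL
  list(occ = out, excluded = excluded)
}

#' Full occurrence-preparation chain
#'
#' dedupe on the fine grid, trim to native ranges, apply the minimum-records
#' filter on the trimmed (pre-thinning) counts, then thin to one record per
#' 40 km block. The filter precedes thinning so a species' eligibility
#' reflects its full cleaned record set, not the thinned one.
#'
#' @param occ Occurrence data frame.
#' @param grid Fine analysis [grid_spec()].
#' @param masks Named list of native-range masks (NULL disables trimming).
#' @param keep_all Species exempt from trimming.
#' @param block_size Thinning block edge (map units).
#' @param min_n Minimum records per species.
#' @param seed Thinning seed.
#' @return List: `occ` (prepared table), `excluded` (species dropped by the
#'   filter), `n_stage` (record counts after each stage).
#' @export
prep_occurrences <- function(occ, grid, masks = NULL,
                             keep_all = character(0), block_size = 40000,
                             min_n = 30, seed = 1) {
  d <- dedupe_per_cell(occ, grid)
  t <- if (is.null(masks)) d else trim_to_native_range(d, masks, keep_all)
  f <- filter_min_occurrences(t, min_n)
  th <- thin_by_block(f$occ, grid, block_size, seed)
  list(occ = th, excluded = f$excluded,
       n_stage = c(input = nrow(occ), deduped = nrow(d), trimmed = nrow(t),
                   filtered = nrow(f$occ), thinned = nrow(th)))
}
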