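#' Grid specification
#'
#' Describes a north-up rectilinear grid in map coordinates using
#' GeoTIFF-style geotransform semantics: cell (1,1) is the top-left cell,
#' `origin_x`/`origin_y` are the coordinates of the top-left *corner* of that
#' cell, and cell centres sit at `origin + (index - 0.5) * cell_size`.
#' `cell_size_y` is negative for a north-up grid. Cells are half-open
#' intervals `[edge, edge + size)`.
#'
#' @param origin_x,origin_y Map coordinates of the top-left corner.
#' @param cell_size_x Cell width in map units (positive).
#' @param cell_size_y Cell height in map units (negative for north-up).
#' @param n_cols,n_rows Grid dimensions (>= 1).
#' @param crs_tag Opaque coordinate-reference identifier (e.g. "EPSG:3035").
#'   No reprojection is ever performed; the tag is carried through I/O.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(origin_x, origin_y, cell_size_x, cell_size_y,
                      n_cols, n_rows, crs_tag = "local") {
  stopifnot(n_cols >= 1, n_rows >= 1, cell_size_x != 0, cell_size_y != 0)
  structure(
    list(origin_x = as.numeric(origin_x), origin_y = as.numeric(origin_y),
         cell_size_x = as.numeric(cell_size_x),
         cell_size_y = as.numeric(cell_size_y),
         n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
         crs_tag = as.character(crs_tag)),
    class = "grid_spec")
}

#' @exportS3Method base::print
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d cols x %d rows, cell %g x %g, origin (%g, %g), crs %s\n",
              x$n_cols, x$n_rows, x$cell_size_x, x$cell_size_y,
              x$origin_x, x$origin_y, x$crs_tag))
  invisible(x)
}

grids_equal <- function(a, b, tol = 1e-9) {
  a$n_cols == b$n_cols && a$n_rows == b$n_rows &&
    abs(a$origin_x - b$origin_x) < tol && abs(a$origin_y - b$origin_y) < tol &&
    abs(a$cell_size_x - b$cell_size_x) < tol &&
    abs(a$cell_size_y - b$cell_size_y) < tol
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return List with `x` (length `n_cols`) and `y` (length `n_rows`) centre
#'   coordinates; `y` runs north to south (row 1 first).
#' @export
cell_centres <- function(grid) {
  list(x = grid$origin_x + (seq_len(grid$n_cols) - 0.5) * grid$cell_size_x,
       y = grid$origin_y + (seq_len(grid$n_rows) - 0.5) * grid$cell_size_y)
}

#' Map coordinates to cell indices
#'
#' Half-open cell convention: a point on a shared edge belongs to the cell
#' whose lower-index edge it is.
#'
#' @param grid A [grid_spec()].
#' @param x,y Coordinate vectors.
#' @return Data frame with integer `col`, `row` (NA outside the grid) and
#'   logical `inside`.
#' @export
cell_index <- function(grid, x, y) {
  col <- floor((x - grid$origin_x) / grid$cell_size_x) + 1
  row <- floor((y - grid$origin_y) / grid$cell_size_y) + 1
  inside <- !is.na(col) & !is.na(row) &
    col >= 1 & col <= grid$n_cols & row >= 1 & row <= grid$n_rows
  col[!inside] <- NA_integer_
  row[!inside] <- NA_integer_
  data.frame(col = as.integer(col), row = as.integer(row), inside = inside)
}

#' Construct a raster
#'
#' A raster couples a [grid_spec()] with an `n_rows x n_cols` numeric matrix.
#' Missing cells are held as `NA` in memory; `nodata` records the sentinel
#' used when the raster is written to disk. Arithmetic is never performed on
#' the sentinel: it exists only at the I/O boundary.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix (`n_rows` x `n_cols`) or a scalar to fill.
#' @param nodata Sentinel value used on disk (default -9999).
#' @return An object of class `tr_raster`.
#' @export
make_raster <- function(grid, values, nodata = -9999) {
  if (length(values) == 1) {
    values <- matrix(values, nrow = grid$n_rows, ncol = grid$n_cols)
  }
  stopifnot(is.matrix(values),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  dimnames(values) <- NULL
  structure(list(grid = grid, values = values, nodata = nodata),
            class = "tr_raster")
}

#' @exportS3Method base::print
print.tr_raster <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat(sprintf("<tr_raster> %d x %d, %d valid cells, range [%g, %g]\n",
              x$grid$n_rows, x$grid$n_cols, length(v),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Construct a raster stack
#'
#' An ordered, named collection of rasters sharing one grid.
#'
#' @param layers Named list of `tr_raster` objects on a common grid.
#' @return An object of class `tr_stack`.
#' @export
raster_stack <- function(layers) {
  stopifnot(is.list(layers), length(layers) >= 1,
            !is.null(names(layers)), !anyDuplicated(names(layers)))
  g <- layers[[1]]$grid
  for (l in layers) {
    if (!grids_equal(l$grid, g)) stop("all stack layers must share one grid")
  }
  structure(list(grid = g, layers = layers), class = "tr_stack")
}

#' @exportS3Method base::print
print.tr_stack <- function(x, ...) {
  cat(sprintf("<tr_stack> %d layers on %d x %d grid: %s\n",
              length(x$layers), x$grid$n_rows, x$grid$n_cols,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' @rdname raster_stack
#' @param x A `tr_stack`.
#' @export
stack_names <- function(x) names(x$layers)

#' Flatten a stack to a cell-by-layer matrix
#'
#' Cells are ordered row-major (row 1 west-to-east first), matching the
#' raster writing order on disk.
#'
#' @param x A `tr_stack`.
#' @param layers Optional subset of layer names.
#' @return Numeric matrix with one column per layer.
#' @export
stack_as_matrix <- function(x, layers = NULL) {
  if (is.null(layers)) layers <- stack_names(x)
  m <- vapply(layers, function(nm) as.vector(t(x$layers[[nm]]$values)),
              numeric(x$grid$n_rows * x$grid$n_cols))
  if (!is.matrix(m)) m <- matrix(m, nrow = 1)
  dimnames(m) <- list(NULL, layers)
  m
}

#' Extract layer values at point coordinates
#'
#' Values are read from the cell containing each point (no interpolation),
#' matching how point occurrences are matched to gridded predictors.
#'
#' @param x A `tr_stack`.
#' @param px,py Point coordinates.
#' @param layers Optional subset of layer names.
#' @return Matrix of values (rows = points); NA outside the grid.
#' @export
stack_extract <- function(x, px, py, layers = NULL) {
  if (is.null(layers)) layers <- stack_names(x)
  idx <- cell_index(x$grid, px, py)
  m <- matrix(NA_real_, nrow = length(px), ncol = length(layers),
              dimnames = list(NULL, layers))
  ok <- idx$inside
  for (nm in layers) {
    m[ok, nm] <- x$layers[[nm]]$values[cbind(idx$row[ok], idx$col[ok])]
  }
  m
}

# ---- ESRI ASCII grid I/O ------------------------------------------------

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text `.asc` format (ncols/nrows/xllcorner/yllcorner/cellsize/
#' NODATA_value header, rows north to south). Requires square cells, as the
#' format does. The CRS tag is written to a `<path>.crs` sidecar when it is
#' not "local".
#'
#' @param r A `tr_raster`.
#' @param path Output path.
#' @param digits Significant digits for floating-point output (ignored for
#'   integer-valued rasters, which are written exactly).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(r, path, digits = 10) {
  g <- r$grid
  if (abs(abs(g$cell_size_x) - abs(g$cell_size_y)) > 1e-9 * abs(g$cell_size_x))
    stop("ESRI ASCII grids require square cells")
  v <- r$values
  v[is.na(v)] <- r$nodata
  yll <- g$origin_y + g$n_rows * g$cell_size_y  # bottom edge (cell_size_y < 0)
  header <- c(
    sprintf("ncols %d", g$n_cols),
    sprintf("nrows %d", g$n_rows),
    sprintf("xllcorner %.10g", g$origin_x),
    sprintf("yllcorner %.10g", yll),
    sprintf("cellsize %.10g", abs(g$cell_size_x)),
    sprintf("NODATA_value %.10g", r$nodata))
  is_int <- all(v == round(v))
  fmt <- if (is_int) "%d" else paste0("%.", digits, "g")
  body <- apply(v, 1, function(row) {
    paste(sprintf(fmt, if (is_int) as.integer(row) else row), collapse = " ")
  })
  writeLines(c(header, body), path)
  if (!identical(g$crs_tag, "local")) writeLines(g$crs_tag, paste0(path, ".crs"))
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path Path to a `.asc` file written by [write_ascii_grid()] or any
#'   conforming writer. A `<path>.crs` sidecar, if present, supplies the CRS
#'   tag.
#' @return A `tr_raster`; cells equal to the file's NODATA_value become `NA`.
#' @export
read_ascii_grid <- function(path) {
  if (!file.exists(path)) stop("cannot read raster: no such file: ", path)
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+[-0-9.eE+]+\\s*$", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr)))
    stop("malformed ASCII grid header in ", path,
         " (missing ", paste(setdiff(need, names(hdr)), collapse = ", "), ")")
  if (!("xllcorner" %in% names(hdr)) || !("yllcorner" %in% names(hdr)))
    stop("ASCII grid ", path, " lacks a georeference (xllcorner/yllcorner)")
  nc <- as.integer(hdr$ncols); nr <- as.integer(hdr$nrows)
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != nc * nr)
    stop("ASCII grid ", path, ": expected ", nc * nr, " values, got ",
         length(vals))
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  m[m == nodata] <- NA
  crs <- "local"
  crs_path <- paste0(path, ".crs")
  if (file.exists(crs_path)) crs <- readLines(crs_path, n = 1)
  g <- grid_spec(hdr$xllcorner, hdr$yllcorner + nr * hdr$cellsize,
                 hdr$cellsize, -hdr$cellsize, nc, nr, crs_tag = crs)
  make_raster(g, m, nodata = nodata)
}

#' Write a raster stack as a directory of ASCII grids with a manifest
#'
#' One `.asc` file per layer plus a plain-text `manifest.txt` recording layer
#' order, file names and the CRS tag, so the multi-layer read restores band
#' order exactly.
#'
#' @param x A `tr_stack`.
#' @param dir Output directory (created if needed).
#' @param digits Passed to [write_ascii_grid()].
#' @return `dir`, invisibly.
#' @export
write_stack <- function(x, dir, digits = 10) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nms <- stack_names(x)
  files <- paste0(gsub("[^A-Za-z0-9_.-]", "_", nms), ".asc")
  for (k in seq_along(nms)) {
    write_ascii_grid(x$layers[[nms[k]]], file.path(dir, files[k]),
                     digits = digits)
  }
  writeLines(c(paste0("crs\t", x$grid$crs_tag),
               paste0(nms, "\t", files)),
             file.path(dir, "manifest.txt"))
  invisible(dir)
}

#' Read a raster stack written by [write_stack()]
#'
#' @param dir Directory containing `manifest.txt` and the layer files.
#' @return A `tr_stack` with layers in manifest order.
#' @export
read_stack <- function(dir) {
  mf <- file.path(dir, "manifest.txt")
  if (!file.exists(mf)) stop("cannot read stack: no manifest in ", dir)
  lines <- strsplit(readLines(mf), "\t")
  crs <- "local"
  layers <- list()
  for (kv in lines) {
    if (kv[1] == "crs") { crs <- kv[2]; next }
    r <- read_ascii_grid(file.path(dir, kv[2]))
    r$grid$crs_tag <- crs
    layers[[kv[1]]] <- r
  }
  raster_stack(layers)
}

# ---- Resampling ---------------------------------------------------------

#' Bilinear regridding between cell-centre registered grids
#'
#' Each destination cell-centre value is the bilinear interpolation of the
#' four surrounding source cell-centres. Destination centres outside the
#' hull of source centres are clamped to the nearest source centre
#' coordinate (so a fine grid spanning the same extent as a coarse grid is
#' fully populated). Any NA among the contributing source cells propagates
#' NA.
#'
#' @param src A `tr_raster`.
#' @param dst_grid Target [grid_spec()].
#' @return A `tr_raster` on `dst_grid`.
#' @export
bilinear_regrid <- function(src, dst_grid) {
  sg <- src$grid
  sc <- cell_centres(sg)
  dc <- cell_centres(dst_grid)
  # overlap check on extents
  sx <- sort(c(sg$origin_x, sg$origin_x + sg$n_cols * sg$cell_size_x))
  sy <- sort(c(sg$origin_y, sg$origin_y + sg$n_rows * sg$cell_size_y))
  dx <- sort(c(dst_grid$origin_x,
               dst_grid$origin_x + dst_grid$n_cols * dst_grid$cell_size_x))
  dy <- sort(c(dst_grid$origin_y,
               dst_grid$origin_y + dst_grid$n_rows * dst_grid$cell_size_y))
  if (dx[2] <= sx[1] || dx[1] >= sx[2] || dy[2] <= sy[1] || dy[1] >= sy[2])
    stop("bilinear_regrid: source and destination extents are disjoint")

  # fractional source-centre coordinates of destination centres, clamped
  fx <- (dc$x - sc$x[1]) / sg$cell_size_x          # 0 .. n_cols-1
  fy <- (dc$y - sc$y[1]) / sg$cell_size_y          # both negative steps cancel
  fx <- pmin(pmax(fx, 0), sg$n_cols - 1)
  fy <- pmin(pmax(fy, 0), sg$n_rows - 1)
  j0 <- pmin(floor(fx), sg$n_cols - 2); j0 <- pmax(j0, 0)
  i0 <- pmin(floor(fy), sg$n_rows - 2); i0 <- pmax(i0, 0)
  if (sg$n_cols == 1) j0 <- rep(0, length(fx))
  if (sg$n_rows == 1) i0 <- rep(0, length(fy))
  wx <- fx - j0
  wy <- fy - i0
  j1 <- pmin(j0 + 1, sg$n_cols - 1)
  i1 <- pmin(i0 + 1, sg$n_rows - 1)

  V <- src$values
  nrd <- dst_grid$n_rows; ncd <- dst_grid$n_cols
  I0 <- matrix(i0 + 1, nrow = nrd, ncol = ncd)
  I1 <- matrix(i1 + 1, nrow = nrd, ncol = ncd)
  J0 <- matrix(j0 + 1, nrow = nrd, ncol = ncd, byrow = TRUE)
  J1 <- matrix(j1 + 1, nrow = nrd, ncol = ncd, byrow = TRUE)
  WY <- matrix(wy, nrow = nrd, ncol = ncd)
  WX <- matrix(wx, nrow = nrd, ncol = ncd, byrow = TRUE)
  v00 <- matrix(V[cbind(as.vector(I0), as.vector(J0))], nrd, ncd)
  v01 <- matrix(V[cbind(as.vector(I0), as.vector(J1))], nrd, ncd)
  v10 <- matrix(V[cbind(as.vector(I1), as.vector(J0))], nrd, ncd)
  v11 <- matrix(V[cbind(as.vector(I1), as.vector(J1))], nrd, ncd)
  out <- (1 - WY) * ((1 - WX) * v00 + WX * v01) +
    WY * ((1 - WX) * v10 + WX * v11)
  # NA in any contributing neighbour poisons the result (arithmetic above
  # already yields NA even at zero weight, which is the documented rule)
  make_raster(dst_grid, out, nodata = src$nodata)
}

#' Area-weighted aggregation of a fraction raster
#'
#' Each destination cell value is the exact area-weighted mean of the source
#' cells overlapping it (general misaligned grids supported via 1-D interval
#' overlaps). Intended for cover fractions in [0, 1]; output stays in [0, 1].
#' NA source cells are excluded from the mean; a destination cell with no
#' valid overlap is NA.
#'
#' @param src A `tr_raster` with values in [0, 1] (finer grid).
#' @param dst_grid Target [grid_spec()] with larger cells.
#' @return A `tr_raster` on `dst_grid`.
#' @export
aggregate_fraction <- function(src, dst_grid) {
  sg <- src$grid
  if (abs(sg$cell_size_x) > abs(dst_grid$cell_size_x) + 1e-12 ||
      abs(sg$cell_size_y) > abs(dst_grid$cell_size_y) + 1e-12)
    stop("aggregate_fraction: source must be finer than destination")

  # 1-D overlap weights between source and destination cell intervals
  overlaps_1d <- function(s_edge0, s_step, s_n, d_edge0, d_step, d_n) {
    s_lo <- s_edge0 + (seq_len(s_n) - 1) * s_step
    s_hi <- s_lo + s_step
    if (s_step < 0) { tmp <- s_lo; s_lo <- s_hi; s_hi <- tmp }
    d_lo <- d_edge0 + (seq_len(d_n) - 1) * d_step
    d_hi <- d_lo + d_step
    if (d_step < 0) { tmp <- d_lo; d_lo <- d_hi; d_hi <- tmp }
    lapply(seq_len(d_n), function(k) {
      w <- pmin(s_hi, d_hi[k]) - pmax(s_lo, d_lo[k])
      idx <- which(w > 1e-12 * abs(s_step))
      list(idx = idx, w = w[idx])
    })
  }
  ox <- overlaps_1d(sg$origin_x, sg$cell_size_x, sg$n_cols,
                    dst_grid$origin_x, dst_grid$cell_size_x, dst_grid$n_cols)
  oy <- overlaps_1d(sg$origin_y, sg$cell_size_y, sg$n_rows,
                    dst_grid$origin_y, dst_grid$cell_size_y, dst_grid$n_rows)
  V <- src$values
  out <- matrix(NA_real_, dst_grid$n_rows, dst_grid$n_cols)
  for (r in seq_len(dst_grid$n_rows)) {
    ry <- oy[[r]]
    if (!length(ry$idx)) next
    for (c in seq_len(dst_grid$n_cols)) {
      rx <- ox[[c]]
      if (!length(rx$idx)) next
      sub <- V[ry$idx, rx$idx, drop = FALSE]
      W <- outer(ry$w, rx$w)
      ok <- !is.na(sub)
      tw <- sum(W[ok])
      if (tw > 0) out[r, c] <- sum(sub[ok] * W[ok]) / tw
    }
  }
  make_raster(dst_grid, out, nodata = src$nodata)
}

#' Block-mean coarsening of a raster
#'
#' Aggregates by an integer factor (dimensions must divide evenly); used to
#' build coarse pseudo-RCM control grids from a fine world.
#'
#' @param r A `tr_raster`.
#' @param factor Integer >= 2.
#' @return A `tr_raster` on the coarsened grid.
#' @export
block_mean <- function(r, factor) {
  g <- r$grid
  factor <- as.integer(factor)
  stopifnot(factor >= 2)
  if (g$n_rows %% factor != 0 || g$n_cols %% factor != 0)
    stop("block_mean: grid dimensions must be divisible by the factor")
  nr <- g$n_rows %/% factor; nc <- g$n_cols %/% factor
  V <- r$values
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1) * factor + 1):(i * factor)
    sub <- V[rows, , drop = FALSE]
    # column-block means
    cm <- matrix(sub, nrow = factor * factor)
    dim(cm) <- c(factor, g$n_cols)
    # mean over factor x factor blocks
    for (j in seq_len(nc)) {
      cols <- ((j - 1) * factor + 1):(j * factor)
      out[i, j] <- mean(V[rows, cols])
    }
  }
  cg <- grid_spec(g$origin_x, g$origin_y,
                  g$cell_size_x * factor, g$cell_size_y * factor,
                  nc, nr, crs_tag = g$crs_tag)
  make_raster(cg, out, nodata = r$nodata)
}

#' Expand a coarse raster to a fine grid by block replication
#'
#' Inverse companion of [block_mean()] for conservation checks.
#'
#' @param r Coarse `tr_raster`.
#' @param factor Integer expansion factor.
#' @return A `tr_raster` on the refined grid.
#' @export
block_expand <- function(r, factor) {
  g <- r$grid
  factor <- as.integer(factor)
  V <- r$values[rep(seq_len(g$n_rows), each = factor),
                rep(seq_len(g$n_cols), each = factor), drop = FALSE]
  fg <- grid_spec(g$origin_x, g$origin_y,
                  g$cell_size_x / factor, g$cell_size_y / factor,
                  g$n_cols * factor, g$n_rows * factor, crs_tag = g$crs_tag)
  make_raster(fg, V, nodata = r$nodata)
}
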