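test_that("ASCII grid round-trip preserves values, grid and nodata", {
  g <- tiny_grid(3, 3, crs = "EPSG:3035")
  r <- make_raster(g, matrix(1, 3, 3))
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  r2 <- read_ascii_grid(path)
  expect_identical(r2$values, r$values)
  expect_equal(r2$grid[c("origin_x", "origin_y", "cell_size_x",
                         "cell_size_y", "n_cols", "n_rows")],
               r$grid[c("origin_x", "origin_y", "cell_size_x",
                        "cell_size_y", "n_cols", "n_rows")])
  expect_identical(r2$grid$crs_tag, "EPSG:3035")

  # integer rasters are bit-exact; floats round-trip within 1e-7
  ri <- make_raster(g, matrix(as.numeric(1:9), 3, 3))
  write_ascii_grid(ri, path)
  expect_identical(read_ascii_grid(path)$values, ri$values)
  rf <- make_raster(g, matrix(sqrt(1:9), 3, 3))
  write_ascii_grid(rf, path)
  expect_lt(max(abs(read_ascii_grid(path)$values - rf$values)), 1e-7)
})

test_that("nodata cells survive a write/read cycle as masked cells", {
  g <- tiny_grid(3, 3)
  v <- matrix(5, 3, 3)
  v[2, 2] <- NA
  r <- make_raster(g, v, nodata = -9999)
  path <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(r, path)
  r2 <- read_ascii_grid(path)
  expect_identical(sum(is.na(r2$values)), 1L)
  expect_true(is.na(r2$values[2, 2]))
})

test_that("multi-layer stacks restore layer order and values", {
  g <- tiny_grid(4, 3)
  s <- raster_stack(list(first = make_raster(g, matrix(as.numeric(1:12), 3, 4)),
                         second = make_raster(g, matrix(as.numeric(12:1), 3, 4))))
  dir <- withr::local_tempdir()
  write_stack(s, dir)
  s2 <- read_stack(dir)
  expect_identical(stack_names(s2), c("first", "second"))
  expect_identical(s2$layers$first$values, s$layers$first$values)
  expect_identical(s2$layers$second$values, s$layers$second$values)
})

test_that("reading a missing or malformed raster fails with the path named", {
  expect_error(read_ascii_grid("/nonexistent/file.asc"), "file")
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "cellsize 1", "1 2", "3 4"), path)
  expect_error(read_ascii_grid(path), "georeference")
})

test_that("bilinear regridding reproduces constants and affine ramps", {
  sg <- grid_spec(0, 100, 10, -10, 10, 10)
  dg <- grid_spec(5, 95, 4, -4, 20, 20)
  cst <- bilinear_regrid(make_raster(sg, matrix(7.5, 10, 10)), dg)
  expect_true(all(cst$values == 7.5))

  cc <- cell_centres(sg)
  ramp <- outer(cc$y, cc$x, function(y, x) 2 * x - 0.5 * y + 3)
  out <- bilinear_regrid(make_raster(sg, ramp), dg)
  dc <- cell_centres(dg)
  want <- outer(dc$y, dc$x, function(y, x) 2 * x - 0.5 * y + 3)
  expect_lt(max(abs(out$values - want)), 1e-9)
})

test_that("a nodata source cell poisons exactly its interpolation neighbourhood", {
  sg <- grid_spec(0, 60, 10, -10, 6, 6)
  v <- matrix(1, 6, 6)
  v[3, 4] <- NA
  dg <- grid_spec(0, 60, 5, -5, 12, 12)
  out <- bilinear_regrid(make_raster(sg, v), dg)
  # brute-force oracle: a destination cell is NA iff the nodata source cell
  # is among the (clamped) 2x2 source centres enclosing its centre
  sc <- cell_centres(sg)
  dc <- cell_centres(dg)
  for (i in seq_len(12)) for (j in seq_len(12)) {
    fx <- min(max((dc$x[j] - sc$x[1]) / 10, 0), 5)
    fy <- min(max((dc$y[i] - sc$y[1]) / (sc$y[2] - sc$y[1]), 0), 5)
    j0 <- min(floor(fx), 4); i0 <- min(floor(fy), 4)
    touches <- (3 - 1) %in% c(i0, i0 + 1) && (4 - 1) %in% c(j0, j0 + 1)
    expect_identical(is.na(out$values[i, j]), touches,
                     label = sprintf("cell (%d,%d)", i, j))
  }
})

test_that("disjoint extents are rejected", {
  sg <- grid_spec(0, 100, 10, -10, 10, 10)
  dg <- grid_spec(1e6, 100, 10, -10, 10, 10)
  expect_error(bilinear_regrid(make_raster(sg, matrix(1, 10, 10)), dg),
               "disjoint")
})

test_that("fraction aggregation averages blocks and matches the overlap oracle", {
  sg <- grid_spec(0, 20, 10, -10, 2, 2)
  dg <- grid_spec(0, 20, 20, -20, 1, 1)
  r <- make_raster(sg, matrix(c(0, 1, 0, 1), 2, 2))
  expect_equal(aggregate_fraction(r, dg)$values[1, 1], 0.5)
  ones <- make_raster(sg, matrix(1, 2, 2))
  expect_true(all(aggregate_fraction(ones, dg)$values == 1))

  # misaligned 3:2 cell-size ratio against an exact rectangle-overlap oracle
  sg2 <- grid_spec(0, 12, 2, -2, 9, 6)
  set.seed(5)
  vals <- matrix(stats::runif(54), 6, 9)
  src <- make_raster(sg2, vals)
  dg2 <- grid_spec(1, 11, 3, -3, 5, 3)
  out <- aggregate_fraction(src, dg2)
  for (i in seq_len(3)) for (j in seq_len(5)) {
    dx0 <- 1 + (j - 1) * 3; dx1 <- dx0 + 3
    dy1 <- 11 - (i - 1) * 3; dy0 <- dy1 - 3
    num <- 0; den <- 0
    for (si in seq_len(6)) for (sj in seq_len(9)) {
      sx0 <- (sj - 1) * 2; sx1 <- sx0 + 2
      sy1 <- 12 - (si - 1) * 2; sy0 <- sy1 - 2
      a <- max(0, min(sx1, dx1) - max(sx0, dx0)) *
        max(0, min(sy1, dy1) - max(sy0, dy0))
      num <- num + a * vals[si, sj]
      den <- den + a
    }
    expect_lt(abs(out$values[i, j] - num / den), 1e-9)
  }
})

test_that("aggregation rejects a source coarser than the destination", {
  sg <- grid_spec(0, 20, 20, -20, 1, 1)
  dg <- grid_spec(0, 20, 10, -10, 2, 2)
  expect_error(aggregate_fraction(make_raster(sg, matrix(1, 1, 1)), dg),
               "finer")
})

test_that("aggregation conserves the global mean on nested grids", {
  sg <- grid_spec(0, 120, 10, -10, 12, 12)
  set.seed(9)
  r <- make_raster(sg, matrix(stats::runif(144), 12, 12))
  dg <- grid_spec(0, 120, 30, -30, 4, 4)
  out <- aggregate_fraction(r, dg)
  expect_lt(abs(mean(out$values) - mean(r$values)), 1e-12)
})

test_that("block mean and block expand are consistent", {
  g <- tiny_grid(4, 4, cell = 10)
  set.seed(3)
  r <- make_raster(g, matrix(stats::runif(16), 4, 4))
  cm <- block_mean(r, 2)
  expect_equal(cm$values[1, 1], mean(r$values[1:2, 1:2]))
  back <- block_expand(cm, 2)
  expect_equal(block_mean(back, 2)$values, cm$values)
  expect_error(block_mean(r, 3), "divisible")
})

test_that("cell indexing follows the half-open cell convention", {
  g <- tiny_grid(3, 3, cell = 10)
  idx <- cell_index(g, c(0, 9.999, 10, 35), c(30, 30, 30, 0.5))
  expect_equal(idx$col, c(1L, 1L, 2L, NA))
  expect_equal(idx$row[1:3], c(1L, 1L, 1L))
  expect_false(idx$inside[4])
})
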