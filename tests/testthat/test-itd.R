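test_that("window radius follows the linear height rule", {
  p <- itdParams()
  expect_equal(windowRadius(12.5, p), 2.0)
  expect_equal(windowRadius(0, p), 0.5)
  expect_equal(windowRadius(2, p), 0.74)
  capped <- itdParams(max_win_diameter = 3)
  expect_equal(windowRadius(20, capped), 1.5)
  expect_error(itdParams(min_height = -1))
})

test_that("a lone peak is the only treetop and carries its CHM height", {
  m <- matrix(0, 21, 21)
  m[11, 11] <- 10
  chm <- rasterGrid(m, origin = c(0, 21 * 0.25), cell_size = 0.25)
  tops <- detectTreetops(chm)
  expect_equal(nrow(tops), 1L)
  expect_equal(tops$height, 10)
  cc <- cellCenters(chm)
  expect_equal(c(tops$x, tops$y), c(cc$x[11], cc$y[11]))
  expect_equal(tops$source, "ALS")
})

test_that("equal peaks inside one window resolve to the first in row-major order", {
  m <- matrix(0, 21, 21)
  m[11, 11] <- 10
  m[11, 15] <- 10  # 4 cells = 1.0 m apart, radius 1.7 m windows overlap
  chm <- rasterGrid(m, origin = c(0, 21 * 0.25), cell_size = 0.25)
  tops <- detectTreetops(chm)
  expect_equal(nrow(tops), 1L)
  cc <- cellCenters(chm)
  expect_equal(tops$x, cc$x[11])  # the earlier column wins
})

test_that("cells below the height threshold are never treetops", {
  flat <- rasterGrid(matrix(1.9, 10, 10), origin = c(0, 2.5), cell_size = 0.25)
  expect_equal(nrow(detectTreetops(flat)), 0L)
  allna <- rasterGrid(matrix(NA_real_, 5, 5), origin = c(0, 5), cell_size = 1)
  expect_equal(nrow(detectTreetops(allna)), 0L)
})

test_that("detection matches the brute-force definition on random rasters", {
  set.seed(99)
  for (rep_i in 1:50) {
    m <- matrix(round(runif(1600, 0, 30) * 2) / 2, 40, 40)  # 0.5 m plateaus
    m[sample(1600, 300)] <- NA
    chm <- rasterGrid(m, origin = c(0, 40), cell_size = 1)
    tops <- detectTreetops(chm)
    oracle <- itdOracle(m, cell_size = 1)
    got <- if (nrow(tops)) {
      cc <- cellCenters(chm)
      cbind(match(round(tops$y, 6), round(cc$y, 6)),
            match(round(tops$x, 6), round(cc$x, 6)))
    } else NULL
    got <- got[order(got[, 1], got[, 2]), , drop = FALSE]
    oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
    expect_equal(unname(got), unname(oracle), info = paste("raster", rep_i))
  }
})

test_that("raising the height threshold never adds treetops", {
  set.seed(12)
  m <- matrix(runif(900, 0, 20), 30, 30)
  chm <- rasterGrid(m, origin = c(0, 30), cell_size = 1)
  lo <- detectTreetops(chm, itdParams(min_height = 2))
  hi <- detectTreetops(chm, itdParams(min_height = 8))
  key <- function(df) paste(df$x, df$y)
  expect_true(all(key(hi) %in% key(lo)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("every reported treetop dominates its own window (post-hoc check)", {
  set.seed(21)
  m <- matrix(runif(1600, 0, 25), 40, 40)
  chm <- rasterGrid(m, origin = c(0, 40), cell_size = 1)
  tops <- detectTreetops(chm)
  cc <- cellCenters(chm)
  for (k in seq_len(nrow(tops))) {
    r <- windowRadius(tops$height[k])
    d2 <- outer((cc$y - tops$y[k])^2, (cc$x - tops$x[k])^2, "+")
    expect_true(all(m[d2 <= r^2] <= tops$height[k]))
  }
})
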