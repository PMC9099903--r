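#' Rasterize a normalized point cloud into a canopy height model
#'
#' Each cell takes the maximum `z` of the points falling in it under the
#' half-open cell convention (see [RasterGrid-class]); cells with no returns
#' are nodata (`NA`), never 0, so street canyons cannot produce spurious
#' local maxima.
#'
#' @param cloud a [PointCloud-class]
#' @param cell_size cell size in meters (default 0.25)
#' @param extent `c(xmin, ymin, xmax, ymax)`; defaults to the cloud's
#'   bounding box snapped out to whole cells.
#' @return a [RasterGrid-class] CHM
#' @export
rasterizeCHM <- function(cloud, cell_size = 0.25, extent = NULL) {
  p <- cloud@points
  if (is.null(extent)) {
    if (!nrow(p)) stop("empty cloud and no extent given")
    extent <- c(floor(min(p$x) / cell_size) * cell_size,
                floor(min(p$y) / cell_size) * cell_size,
                ceiling(max(p$x) / cell_size) * cell_size,
                ceiling(max(p$y) / cell_size) * cell_size)
  }
  if (extent[3] <= extent[1] || extent[4] <= extent[2])
    stop("degenerate extent")
  nc <- ceiling((extent[3] - extent[1]) / cell_size - 1e-9)
  nr <- ceiling((extent[4] - extent[2]) / cell_size - 1e-9)
  origin <- c(extent[1], extent[2] + nr * cell_size)
  vals <- matrix(NA_real_, nr, nc)
  if (nrow(p)) {
    r <- rasterGrid(vals, origin = origin, cell_size = cell_size)
    ij <- cellIndex(r, p$x, p$y)
    ok <- !is.na(ij[, 1])
    if (any(ok)) {
      lin <- (ij[ok, 2] - 1L) * nr + ij[ok, 1]  # column-major linear index
      mx <- tapply(p$z[ok], lin, max)
      vals[as.integer(names(mx))] <- as.numeric(mx)
    }
  }
  rasterGrid(vals, origin = origin, cell_size = cell_size)
}

#' Smooth a CHM with a mean filter
#'
#' One pass of a `window x window` moving mean that ignores nodata: each
#' valid cell is replaced by the mean of the valid cells in its neighborhood
#' (the window shrinks at raster edges); nodata cells stay nodata.
#'
#' @param chm a [RasterGrid-class]
#' @param window odd window side length in cells (default 3)
#' @return smoothed [RasterGrid-class]
#' @export
smoothCHM <- function(chm, window = 3) {
  if (window %% 2 != 1 || window < 1) stop("window must be odd and >= 1")
  if (window == 1) return(chm)
  v <- chm@values
  nr <- nrow(v); nc <- ncol(v)
  valid <- !is.na(v)
  v0 <- ifelse(valid, v, 0)
  acc <- matrix(0, nr, nc); cnt <- matrix(0, nr, nc)
  half <- (window - 1) / 2
  for (di in -half:half) {
    si <- max(1, 1 + di):min(nr, nr + di)   # source rows shifted by di
    ti <- max(1, 1 - di):min(nr, nr - di)   # target rows
    for (dj in -half:half) {
      sj <- max(1, 1 + dj):min(nc, nc + dj)
      tj <- max(1, 1 - dj):min(nc, nc - dj)
      acc[ti, tj] <- acc[ti, tj] + v0[si, sj]
      cnt[ti, tj] <- cnt[ti, tj] + valid[si, sj]
    }
  }
  out <- matrix(NA_real_, nr, nc)
  has <- valid & cnt > 0
  out[has] <- acc[has] / cnt[has]
  rasterGrid(out, origin = chm@origin, cell_size = chm@cellSize)
}

#' Clip building footprints out of a CHM
#'
#' Sets every cell whose center lies inside (or on the boundary of) any
#' building polygon to nodata. Values are never changed otherwise.
#'
#' @param chm a [RasterGrid-class]
#' @param buildings list of polygons (two-column coordinate matrices) or
#'   axis-aligned rectangles `c(xmin, ymin, xmax, ymax)`
#' @param buffer additional clearance in meters: cells whose center lies
#'   within `buffer` of a footprint are removed too. A CHM smoothed with a
#'   `w x w` kernel carries roof heights up to `(w+1)/2` cells beyond the
#'   wall (the wall-straddling cell plus the kernel reach), so a buffer of
#'   two cell sizes removes every roof-contaminated cell at the default
#'   3x3 smoothing; the default 0 clips the literal footprint only.
#' @return clipped [RasterGrid-class]
#' @export
clipBuildings <- function(chm, buildings, buffer = 0) {
  if (!length(buildings)) return(chm)
  v <- chm@values
  cc <- cellCenters(chm)
  for (poly in buildings) {
    if (!is.matrix(poly)) poly <- rectToPolygon(poly)
    if (nrow(poly) < 3 || anyNA(poly)) stop("invalid polygon geometry")
    # restrict the test to cells inside the polygon's (buffered) bounding box
    jj <- which(cc$x >= min(poly[, 1]) - buffer - 1e-9 &
                cc$x <= max(poly[, 1]) + buffer + 1e-9)
    ii <- which(cc$y >= min(poly[, 2]) - buffer - 1e-9 &
                cc$y <= max(poly[, 2]) + buffer + 1e-9)
    if (!length(ii) || !length(jj)) next
    px <- rep(cc$x[jj], each = length(ii))
    py <- rep(cc$y[ii], times = length(jj))
    hit <- pointInPolygon(px, py, poly)
    if (buffer > 0 && !all(hit)) {
      dmin <- rep(Inf, length(px))
      n <- nrow(poly)
      for (k in seq_len(n)) {
        b <- poly[if (k == n) 1 else k + 1, ]
        dmin <- pmin(dmin, distPointToSegment(px, py, poly[k, ], b))
      }
      hit <- hit | dmin <= buffer
    }
    if (any(hit)) {
      sub <- v[ii, jj, drop = FALSE]
      sub[matrix(hit, length(ii), length(jj))] <- NA_real_
      v[ii, jj] <- sub
    }
  }
  rasterGrid(v, origin = chm@origin, cell_size = chm@cellSize)
}
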