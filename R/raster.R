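#' Create a RasterGrid
#'
#' @param values numeric matrix (row 1 = north edge); `NA` is nodata.
#' @param origin numeric(2) top-left (north-west) corner coordinates, meters.
#' @param cell_size square cell size in meters.
#' @return a [RasterGrid-class]
#' @examples
#' r <- rasterGrid(matrix(0, 4, 4), origin = c(0, 1), cell_size = 0.25)
#' gridDim(r)
#' @export
rasterGrid <- function(values, origin = c(0, nrow(values) * cell_size),
                       cell_size = 0.25) {
  storage.mode(values) <- "double"
  new("RasterGrid", origin = as.numeric(origin),
      cellSize = as.numeric(cell_size), values = values)
}

#' @rdname RasterGrid-class
#' @export
setMethod("gridOrigin", "RasterGrid", function(x) x@origin)

#' @rdname RasterGrid-class
#' @export
setMethod("cellSize", "RasterGrid", function(x) x@cellSize)

#' @rdname RasterGrid-class
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @rdname RasterGrid-class
#' @export
setMethod("gridDim", "RasterGrid", function(x) dim(x@values))

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  v <- object@values[!is.na(object@values)]
  cat("RasterGrid:", d[1], "x", d[2], "cells @", object@cellSize, "m\n")
  cat("  origin (top-left):", paste(object@origin, collapse = ", "), "\n")
  if (length(v))
    cat(sprintf("  values: [%.3f, %.3f], %d nodata cells\n",
                min(v), max(v), sum(is.na(object@values))))
  else cat("  values: all nodata\n")
})

#' Cell indices and centers
#'
#' `cellIndex()` maps point coordinates to 1-based (row, col) indices under the
#' half-open cell convention (see [RasterGrid-class]); points outside the grid
#' get `NA`. `cellCenters()` returns the x coordinates of column centers and y
#' coordinates of row centers.
#'
#' @param raster a [RasterGrid-class]
#' @param x,y point coordinates (vectorized)
#' @return `cellIndex`: a two-column integer matrix (row, col);
#'   `cellCenters`: list with elements `x` (length ncol) and `y` (length nrow).
#' @export
cellIndex <- function(raster, x, y) {
  c0 <- raster@origin; cs <- raster@cellSize; d <- dim(raster@values)
  j <- floor((x - c0[1]) / cs) + 1L
  i <- floor((c0[2] - y) / cs) + 1L
  # top edge of the grid is closed (y == origin y belongs to row 1)
  i[(c0[2] - y) == 0] <- 1L
  bad <- i < 1L | i > d[1] | j < 1L | j > d[2]
  i[bad] <- NA_integer_; j[bad] <- NA_integer_
  cbind(row = as.integer(i), col = as.integer(j))
}

#' @rdname cellIndex
#' @export
cellCenters <- function(raster) {
  c0 <- raster@origin; cs <- raster@cellSize; d <- dim(raster@values)
  list(x = c0[1] + (seq_len(d[2]) - 0.5) * cs,
       y = c0[2] - (seq_len(d[1]) - 0.5) * cs)
}

#' Read/write Esri ASCII grid rasters
#'
#' Plain-text single-band raster exchange format (`ncols/nrows/xllcorner/
#' yllcorner/cellsize/NODATA_value` header then row-major values, north row
#' first), readable by GDAL/QGIS.
#'
#' @param raster a [RasterGrid-class]
#' @param path file path (.asc)
#' @param nodata sentinel written for `NA` cells
#' @return `readAsciiGrid` returns a [RasterGrid-class]; `writeAsciiGrid`
#'   returns `path` invisibly.
#' @export
writeAsciiGrid <- function(raster, path, nodata = -9999) {
  d <- dim(raster@values); cs <- raster@cellSize; o <- raster@origin
  hdr <- c(sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10g", o[1]),
           sprintf("yllcorner %.10g", o[2] - d[1] * cs),
           sprintf("cellsize %.10g", cs),
           sprintf("NODATA_value %.10g", nodata))
  v <- raster@values
  v[is.na(v)] <- nodata
  lines <- apply(v, 1, function(r) paste(format(r, trim = TRUE, digits = 10),
                                         collapse = " "))
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' @rdname writeAsciiGrid
#' @export
readAsciiGrid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  vals <- lapply(lines[i:length(lines)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  stopifnot(nrow(m) == hdr$nrows, ncol(m) == hdr$ncols)
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  rasterGrid(m,
             origin = c(hdr$xllcorner, hdr$yllcorner + hdr$nrows * hdr$cellsize),
             cell_size = hdr$cellsize)
}
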