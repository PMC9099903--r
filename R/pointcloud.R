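#' Create a PointCloud
#'
#' @param x,y,z numeric vectors (meters); `z` is normalized height above
#'   ground, so `z >= 0`.
#' @return a [PointCloud-class]
#' @export
pointCloud <- function(x = numeric(), y = numeric(), z = numeric()) {
  new("PointCloud", points = data.frame(x = as.numeric(x), y = as.numeric(y),
                                        z = as.numeric(z)))
}

#' @rdname PointCloud-class
#' @export
setMethod("cloudPoints", "PointCloud", function(x) x@points)

setMethod("show", "PointCloud", function(object) {
  p <- object@points
  cat("PointCloud:", nrow(p), "points\n")
  if (nrow(p))
    cat(sprintf("  extent x [%.2f, %.2f] y [%.2f, %.2f], z max %.2f m\n",
                min(p$x), max(p$x), min(p$y), max(p$y), max(p$z)))
})

#' Read/write XYZ text point clouds
#'
#' Whitespace-separated `x y z` per line, no header: the plain-text exchange
#' format for normalized ALS returns.
#'
#' @param cloud a [PointCloud-class]
#' @param path file path
#' @return `readXYZ` returns a [PointCloud-class].
#' @export
writeXYZ <- function(cloud, path) {
  p <- cloud@points
  writeLines(sprintf("%.4f %.4f %.4f", p$x, p$y, p$z), path)
  invisible(path)
}

#' @rdname writeXYZ
#' @export
readXYZ <- function(path) {
  m <- read.table(path, col.names = c("x", "y", "z"))
  pointCloud(m$x, m$y, m$z)
}
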