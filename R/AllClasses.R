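#' RasterGrid: a georeferenced single-band grid
#'
#' Minimal in-memory raster. `values` is a numeric matrix in row-major reading
#' order with row 1 at the north edge; `origin` is the (x, y) of the top-left
#' corner; `cellSize` the square cell size in meters. `NA` is nodata. Cell
#' (i, j) (1-based) covers the half-open square
#' `[x0 + (j-1)c, x0 + jc) x (y0 - ic, y0 - (i-1)c]`: a point on a shared
#' vertical edge belongs to the cell whose left (west) boundary it is, and a
#' point on a shared horizontal edge belongs to the cell whose top (north)
#' boundary it is, so no point falls in two cells.
#'
#' @slot origin numeric(2), (x, y) of the top-left (north-west) corner.
#' @slot cellSize positive number, cell size in meters.
#' @slot values numeric matrix of cell values; `NA` = nodata.
#' @seealso [rasterGrid()], [cellIndex()], [cellCenters()]
#' @export
setClass("RasterGrid",
  representation(origin = "numeric", cellSize = "numeric", values = "matrix"),
  validity = function(object) {
    msg <- character()
    if (length(object@origin) != 2 || !all(is.finite(object@origin)))
      msg <- c(msg, "origin must be two finite numbers (x, y) of the top-left corner")
    if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
        object@cellSize <= 0)
      msg <- c(msg, "cellSize must be a single positive number")
    if (!is.numeric(object@values))
      msg <- c(msg, "values must be a numeric matrix")
    if (length(msg)) msg else TRUE
  }
)

#' PointCloud: normalized-height ALS returns
#'
#' First-return point cloud with heights already normalized to ground
#' (`z >= 0`; flat terrain is assumed throughout).
#'
#' @slot points data.frame with numeric columns `x`, `y` (meters, planar) and
#'   `z` (meters above ground).
#' @seealso [pointCloud()], [readXYZ()], [rasterizeCHM()]
#' @export
setClass("PointCloud",
  representation(points = "data.frame"),
  validity = function(object) {
    p <- object@points
    if (!all(c("x", "y", "z") %in% names(p)))
      return("points must have columns x, y, z")
    if (nrow(p) && !all(is.finite(p$x) & is.finite(p$y) & is.finite(p$z)))
      return("point coordinates must be finite")
    if (nrow(p) && any(p$z < 0))
      return("normalized heights must satisfy z >= 0")
    TRUE
  }
)

#' OrthoStack: co-registered orthophoto bands
#'
#' A named set of single-band grids sharing one origin, cell size and shape.
#' The canonical band set is two RGB acquisitions plus one near-infrared band:
#' `R14, G14, B14, R17, G17, B17, NIR17`.
#'
#' @slot origin numeric(2), top-left corner shared by all bands.
#' @slot cellSize shared cell size in meters (0.25 by default upstream).
#' @slot bands named list of numeric matrices, identical dimensions.
#' @seealso [orthoStack()], [getBand()], [zonalFeatures()]
#' @export
setClass("OrthoStack",
  representation(origin = "numeric", cellSize = "numeric", bands = "list"),
  validity = function(object) {
    if (length(object@bands) < 1) return("at least one band required")
    if (is.null(names(object@bands)) || any(!nzchar(names(object@bands))))
      return("bands must be named")
    dims <- lapply(object@bands, dim)
    if (length(unique(dims)) != 1)
      return("all bands must share the same dimensions")
    if (length(object@cellSize) != 1 || object@cellSize <= 0)
      return("cellSize must be a single positive number")
    TRUE
  }
)

#' UrbanScene: a synthetic city scene with known ground truth
#'
#' Container produced by [generateScene()] / [simulateScene()]. Ground-truth
#' trees, building footprints, panorama stations and clutter objects are
#' always present; the point cloud, ortho stack and per-image detections are
#' filled by the render/simulate steps (or by [simulateScene()] in one call).
#'
#' @slot config the [sceneConfig()] list the scene was generated from.
#' @slot trees data.frame: `id, x, y, height, crown_radius, zone`
#'   (`zone` is `"street"` or `"park"`).
#' @slot buildings list of polygons (two-column coordinate matrices, closed
#'   implicitly) with a `heights` attribute (meters).
#' @slot clutter data.frame of non-tree raised objects:
#'   `id, x, y, height, radius`.
#' @slot stations data.frame: `id, x, y, heading, pitch, hfov, vfov,
#'   img_width, img_height, camera_height`.
#' @slot cloud a [PointCloud-class] (possibly empty before rendering).
#' @slot ortho an [OrthoStack-class] or NULL-like empty stack.
#' @slot detections data.frame of per-image detections
#'   (`station_id, kind, u, v, confidence, truth_id`).
#' @export
setClass("UrbanScene",
  representation(config = "list", trees = "data.frame", buildings = "list",
                 clutter = "data.frame", stations = "data.frame",
                 cloud = "PointCloud", ortho = "OrthoStack",
                 detections = "data.frame"),
  validity = function(object) {
    tr <- object@trees
    need <- c("id", "x", "y", "height", "crown_radius", "zone")
    if (!all(need %in% names(tr)))
      return("trees must have columns id, x, y, height, crown_radius, zone")
    if (anyDuplicated(tr$id)) return("tree ids must be unique")
    w <- object@config$area_width; h <- object@config$area_height
    if (nrow(tr) && (any(tr$x < 0 | tr$x > w) || any(tr$y < 0 | tr$y > h)))
      return("tree coordinates must lie within the scene area")
    TRUE
  }
)
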