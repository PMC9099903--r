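#' Scene configuration for the synthetic city simulator
#'
#' Builds the seeded configuration that fixes every property of a synthetic
#' urban scene: street layout, tree placement, buildings, non-tree clutter,
#' panorama stations, ALS point density, per-image detection noise and the
#' TREE / NOT-TREE band spectra. Defaults emulate the acquisition conditions
#' the pipeline is designed for: 0.25 m orthophoto pixels, 14 first
#' returns/m2, panorama stations every 15 m at 2.5 m camera height.
#'
#' @param area_width,area_height scene size in meters.
#' @param street_axes list of street centerlines, each a two-column matrix of
#'   polyline vertices (meters).
#' @param street_tree_spacing spacing of street trees along each axis (m).
#'   Trees sit at arc lengths `0, s, 2s, ...`; the far endpoint carries a tree
#'   exactly when the axis length is a multiple of the spacing.
#' @param street_tree_offset lateral sidewalk offset of street trees from the
#'   camera axis (m), alternating sides.
#' @param street_clearance no park tree grows within this distance of a
#'   street axis (m).
#' @param park_tree_density park tree intensity, trees per hectare.
#' @param min_tree_spacing minimum distance between any two trees (m).
#' @param height_range,crown_radius_range uniform ranges for tree height and
#'   crown radius (m), min <= max.
#' @param building_rects list of axis-aligned rectangles
#'   `c(xmin, ymin, xmax, ymax)` (m).
#' @param building_clearance no tree stem within this distance of a building
#'   footprint (m); street trees are planted clear of walls.
#' @param building_height roof height of all buildings (m); gives the point
#'   cloud real roof returns so building clipping matters.
#' @param n_clutter number of raised non-tree objects (lamppost-like) that
#'   inject ALS false positives.
#' @param clutter_height_range,clutter_radius clutter heights (m) and
#'   flat-top radius (m); the radius is wide enough to survive CHM smoothing.
#' @param station_spacing panorama station spacing along street axes (m);
#'   stations start half a spacing from the axis start.
#' @param camera_height panorama camera height above ground (m).
#' @param img_width,img_height panorama pixel dimensions.
#' @param hfov,vfov,pitch horizontal/vertical field of view and camera tilt
#'   (degrees). The default is a full 360 deg equirectangular panorama with a
#'   90 deg perspective vertical field.
#' @param pixel_model `"equirect"` or `"perspective"` horizontal pixel model.
#' @param point_density ALS first returns per m2.
#' @param point_noise_sd additive height noise sd on crown/roof returns (m),
#'   truncated at +-3 sd.
#' @param bearing_noise_sd,distance_noise_sd detection noise (degrees, m).
#' @param detection_miss_rate probability that a visible tree is missed in
#'   one image.
#' @param false_detection_rate expected spurious detections per image
#'   (Poisson). Spurious targets are placed more than 5 m from every true
#'   tree, so injected false positives are unambiguous at inventory level.
#' @param detection_max_range maximum station-to-tree detection range (m).
#' @param spectral_params list with elements `TREE` and `NOT_TREE`, each a
#'   list of `mean` (named per band) and `sd` vectors. Defaults separate the
#'   classes by >10 sd on the near-infrared band.
#' @param n_truth_samples labeled spectral sample points drawn by
#'   [sampleTruthPoints()].
#' @param seed integer; fixes all randomness (each artifact draws from its
#'   own derived stream so sub-steps can be regenerated independently).
#' @return a validated `sceneConfig` list.
#' @seealso [generateScene()], [simulateScene()]
#' @export
sceneConfig <- function(area_width = 200, area_height = 200,
                        street_axes = list(
                          cbind(c(0, 200), c(50, 50)),
                          cbind(c(0, 200), c(150, 150)),
                          cbind(c(50, 50), c(0, 200)),
                          cbind(c(150, 150), c(0, 200))),
                        street_tree_spacing = 10,
                        street_tree_offset = 4,
                        street_clearance = 6,
                        park_tree_density = 20,
                        min_tree_spacing = 6,
                        height_range = c(6, 14),
                        crown_radius_range = c(1.5, 3),
                        building_rects = list(c(65, 60, 85, 80),
                                              c(115, 115, 135, 135),
                                              c(20, 160, 40, 175)),
                        building_height = 9,
                        building_clearance = 2,
                        n_clutter = 25,
                        clutter_height_range = c(3, 8),
                        clutter_radius = 0.8,
                        station_spacing = 15,
                        camera_height = 2.5,
                        img_width = 2048, img_height = 1024,
                        hfov = 360, vfov = 90, pitch = 0,
                        pixel_model = c("equirect", "perspective"),
                        point_density = 14,
                        point_noise_sd = 0.1,
                        bearing_noise_sd = 0.5,
                        distance_noise_sd = 1.0,
                        detection_miss_rate = 0.1,
                        false_detection_rate = 0.5,
                        detection_max_range = 60,
                        spectral_params = defaultSpectralParams(),
                        n_truth_samples = 2000,
                        seed = 1L) {
  cfg <- list(area_width = area_width, area_height = area_height,
              street_axes = street_axes,
              street_tree_spacing = street_tree_spacing,
              street_tree_offset = street_tree_offset,
              street_clearance = street_clearance,
              park_tree_density = park_tree_density,
              min_tree_spacing = min_tree_spacing,
              height_range = height_range,
              crown_radius_range = crown_radius_range,
              building_rects = building_rects,
              building_height = building_height,
              building_clearance = building_clearance,
              n_clutter = n_clutter,
              clutter_height_range = clutter_height_range,
              clutter_radius = clutter_radius,
              station_spacing = station_spacing,
              camera_height = camera_height,
              img_width = img_width, img_height = img_height,
              hfov = hfov, vfov = vfov, pitch = pitch,
              pixel_model = match.arg(pixel_model),
              point_density = point_density,
              point_noise_sd = point_noise_sd,
              bearing_noise_sd = bearing_noise_sd,
              distance_noise_sd = distance_noise_sd,
              detection_miss_rate = detection_miss_rate,
              false_detection_rate = false_detection_rate,
              detection_max_range = detection_max_range,
              spectral_params = spectral_params,
              n_truth_samples = n_truth_samples,
              seed = as.integer(seed))
  validateSceneConfig(cfg)
  class(cfg) <- c("sceneConfig", "list")
  cfg
}

#' Default TREE / NOT-TREE band spectra
#'
#' Seven bands (two RGB acquisitions plus near-infrared). The classes are
#' separated by 12.5 sd on `NIR17` (live vegetation is bright in NIR), with
#' weaker separation on the visible bands.
#' @return list with `TREE` and `NOT_TREE`, each `list(mean=, sd=)`.
#' @export
defaultSpectralParams <- function() {
  bands <- c("R14", "G14", "B14", "R17", "G17", "B17", "NIR17")
  tree <- c(60, 110, 55, 62, 115, 58, 180)
  other <- c(120, 118, 115, 122, 120, 118, 80)
  names(tree) <- names(other) <- bands
  list(TREE = list(mean = tree, sd = stats::setNames(rep(8, 7), bands)),
       NOT_TREE = list(mean = other, sd = stats::setNames(rep(8, 7), bands)))
}

validateSceneConfig <- function(cfg) {
  stopifnot(cfg$area_width > 0, cfg$area_height > 0)
  rng <- function(r) length(r) == 2 && r[1] <= r[2]
  if (!rng(cfg$height_range) || !rng(cfg$crown_radius_range) ||
      !rng(cfg$clutter_height_range))
    stop("ranges must satisfy min <= max")
  if (cfg$detection_miss_rate < 0 || cfg$detection_miss_rate > 1)
    stop("detection_miss_rate must be in [0, 1]")
  if (cfg$false_detection_rate < 0)
    stop("false_detection_rate must be >= 0")
  if (cfg$point_density <= 0) stop("point_density must be positive")
  if (cfg$pixel_model == "perspective" && cfg$hfov >= 180)
    stop("perspective model requires hfov < 180")
  for (cl in c("TREE", "NOT_TREE"))
    if (is.null(cfg$spectral_params[[cl]]))
      stop("spectral_params must define class ", cl)
  invisible(cfg)
}

# ---- polyline helpers -------------------------------------------------------

polylineLength <- function(ax) {
  d <- diff(ax)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

# point and unit direction at arc length s along a polyline
polylinePoint <- function(ax, s) {
  d <- diff(ax)
  seglen <- sqrt(d[, 1]^2 + d[, 2]^2)
  cum <- c(0, cumsum(seglen))
  s <- min(max(s, 0), cum[length(cum)])
  k <- max(which(cum <= s + 1e-12))
  k <- min(k, nrow(d))
  t <- if (seglen[k] > 0) (s - cum[k]) / seglen[k] else 0
  p <- ax[k, ] + t * d[k, ]
  list(p = as.numeric(p), dir = as.numeric(d[k, ] / seglen[k]))
}

distPointToSegment <- function(px, py, a, b) {
  ab <- b - a
  len2 <- sum(ab^2)
  if (len2 == 0) return(sqrt((px - a[1])^2 + (py - a[2])^2))
  t <- pmin(pmax(((px - a[1]) * ab[1] + (py - a[2]) * ab[2]) / len2, 0), 1)
  sqrt((px - (a[1] + t * ab[1]))^2 + (py - (a[2] + t * ab[2]))^2)
}

distToAxes <- function(px, py, axes) {
  d <- rep(Inf, length(px))
  for (ax in axes)
    for (k in seq_len(nrow(ax) - 1))
      d <- pmin(d, distPointToSegment(px, py, ax[k, ], ax[k + 1, ]))
  d
}

insideAnyBuilding <- function(px, py, building_rects) {
  if (!length(building_rects)) return(rep(FALSE, length(px)))
  hit <- rep(FALSE, length(px))
  for (r in building_rects)
    hit <- hit | (px >= r[1] & px <= r[3] & py >= r[2] & py <= r[4])
  hit
}

# ---- scene generation -------------------------------------------------------

#' Generate the layout of a synthetic urban scene
#'
#' Places street trees along each street axis at fixed spacing (offset to the
#' sidewalk, alternating sides), park trees as a thinned Poisson process, and
#' panorama stations along the axes. No tree center falls inside a building
#' rectangle and all trees respect the minimum spacing. Deterministic for a
#' fixed seed. Point cloud, ortho stack and detections are rendered
#' separately ([renderPointCloud()], [renderOrtho()], [simulateDetections()])
#' or all at once by [simulateScene()].
#'
#' @param config a [sceneConfig()]
#' @return an [UrbanScene-class] with empty cloud/ortho/detections slots.
#' @export
generateScene <- function(config) {
  validateSceneConfig(config)
  w <- config$area_width; h <- config$area_height
  withSeed(subSeed(config$seed, 1L), {
    xs <- numeric(); ys <- numeric(); zone <- character()
    # street trees: arc positions 0, s, 2s, ... (far endpoint included iff
    # the axis length is a multiple of the spacing), offset laterally
    for (ax in config$street_axes) {
      L <- polylineLength(ax)
      ss <- seq(0, L + 1e-9, by = config$street_tree_spacing)
      ss <- ss[ss <= L + 1e-9]
      for (k in seq_along(ss)) {
        pp <- polylinePoint(ax, min(ss[k], L))
        side <- if (k %% 2 == 1) 1 else -1
        perp <- c(-pp$dir[2], pp$dir[1]) * side * config$street_tree_offset
        xs <- c(xs, pp$p[1] + perp[1]); ys <- c(ys, pp$p[2] + perp[2])
        zone <- c(zone, "street")
      }
    }
    # park trees: Poisson intensity over the area, rejected near streets
    n_park <- rpois(1, config$park_tree_density * w * h / 1e4)
    if (n_park > 0) {
      px <- runif(n_park, 0, w); py <- runif(n_park, 0, h)
      keep <- distToAxes(px, py, config$street_axes) > config$street_clearance
      xs <- c(xs, px[keep]); ys <- c(ys, py[keep])
      zone <- c(zone, rep("park", sum(keep)))
    }
    # exclusions and greedy min-spacing thinning (street trees first)
    ok <- xs >= 0 & xs <= w & ys >= 0 & ys <= h &
      distToRects(xs, ys, config$building_rects) > config$building_clearance
    xs <- xs[ok]; ys <- ys[ok]; zone <- zone[ok]
    keep <- rep(FALSE, length(xs))
    for (k in seq_along(xs)) {
      if (!any(keep)) { keep[k] <- TRUE; next }
      dmin <- min(sqrt((xs[keep] - xs[k])^2 + (ys[keep] - ys[k])^2))
      keep[k] <- dmin >= config$min_tree_spacing
    }
    xs <- xs[keep]; ys <- ys[keep]; zone <- zone[keep]
    n <- length(xs)
    trees <- data.frame(
      id = sprintf("T%04d", seq_len(n)), x = xs, y = ys,
      height = runif(n, config$height_range[1], config$height_range[2]),
      crown_radius = runif(n, config$crown_radius_range[1],
                           config$crown_radius_range[2]),
      zone = zone, stringsAsFactors = FALSE)

    # clutter: raised non-tree objects, kept clear of trees so they are
    # unambiguous false positives under the 5 m matching rule
    cl <- data.frame(id = character(), x = numeric(), y = numeric(),
                     height = numeric(), radius = numeric())
    if (config$n_clutter > 0) {
      got <- 0; cx <- cy <- numeric()
      tries <- 0
      while (got < config$n_clutter && tries < config$n_clutter * 200) {
        tries <- tries + 1
        qx <- runif(1, 1, w - 1); qy <- runif(1, 1, h - 1)
        if (insideAnyBuilding(qx, qy, config$building_rects)) next
        if (n && min(sqrt((trees$x - qx)^2 + (trees$y - qy)^2)) < 6) next
        if (got && min(sqrt((cx - qx)^2 + (cy - qy)^2)) < 3) next
        got <- got + 1; cx <- c(cx, qx); cy <- c(cy, qy)
      }
      cl <- data.frame(id = sprintf("C%03d", seq_len(got)), x = cx, y = cy,
                       height = runif(got, config$clutter_height_range[1],
                                      config$clutter_height_range[2]),
                       radius = config$clutter_radius,
                       stringsAsFactors = FALSE)
    }

    # stations: offset half a spacing from the axis start, every
    # station_spacing along the axis, heading = direction of travel
    sx <- sy <- hd <- numeric()
    for (ax in config$street_axes) {
      L <- polylineLength(ax)
      ss <- seq(config$station_spacing / 2, L, by = config$station_spacing)
      for (s in ss) {
        pp <- polylinePoint(ax, s)
        sx <- c(sx, pp$p[1]); sy <- c(sy, pp$p[2])
        hd <- c(hd, wrapDeg360(rad2deg(atan2(pp$dir[1], pp$dir[2]))))
      }
    }
    stations <- data.frame(
      id = sprintf("S%03d", seq_along(sx)), x = sx, y = sy, heading = hd,
      pitch = config$pitch, hfov = config$hfov, vfov = config$vfov,
      img_width = config$img_width, img_height = config$img_height,
      camera_height = config$camera_height, capture_date = "2019-06-01",
      stringsAsFactors = FALSE)

    buildings <- lapply(config$building_rects, rectToPolygon)
    attr(buildings, "heights") <- rep(config$building_height,
                                      length(buildings))
    new("UrbanScene", config = unclass(config), trees = trees,
        buildings = buildings, clutter = cl, stations = stations,
        cloud = pointCloud(),
        ortho = orthoStack(list(empty = matrix(NA_real_, 1, 1)),
                           origin = c(0, h), cell_size = 0.25),
        detections = emptyDetections())
  })
}

emptyDetections <- function() {
  data.frame(station_id = character(), kind = character(), u = numeric(),
             v = numeric(), confidence = numeric(), truth_id = character(),
             stringsAsFactors = FALSE)
}

# crown surface height at planar distance d from a tree: solid of revolution
# (paraboloid), apex = tree height, zero at the crown edge
crownSurface <- function(h, R, d) pmax(0, h * (1 - (d / R)^2))

#' Render the ALS point cloud of a scene
#'
#' Uniform first returns over the whole area at the requested density
#' (realized count = `round(density * area)`). Returns under a crown sample
#' the paraboloid crown surface (apex = tree height, zero at the crown edge)
#' plus additive noise truncated at +-3 sd; building rectangles return the
#' roof height, clutter objects their flat top; all remaining returns are
#' ground at exactly z = 0. Heights are normalized (flat terrain).
#'
#' @param scene an [UrbanScene-class]
#' @param density first returns per m2 (default from the scene config)
#' @return a [PointCloud-class]
#' @export
renderPointCloud <- function(scene, density = scene@config$point_density) {
  if (density <= 0) stop("density must be positive")
  cfg <- scene@config
  w <- cfg$area_width; h <- cfg$area_height
  withSeed(subSeed(cfg$seed, 2L), {
    n <- round(density * w * h)
    x <- runif(n, 0, w); y <- runif(n, 0, h)
    z <- numeric(n)
    noise <- function(m) {
      e <- rnorm(m, 0, cfg$point_noise_sd)
      pmin(pmax(e, -3 * cfg$point_noise_sd), 3 * cfg$point_noise_sd)
    }
    if (length(cfg$building_rects)) {
      inb <- insideAnyBuilding(x, y, cfg$building_rects)
      z[inb] <- pmax(0, cfg$building_height + noise(sum(inb)))
    }
    cl <- scene@clutter
    for (k in seq_len(nrow(cl))) {
      d2 <- (x - cl$x[k])^2 + (y - cl$y[k])^2
      hit <- d2 <= cl$radius[k]^2
      z[hit] <- pmax(z[hit], pmax(0, cl$height[k] + noise(sum(hit))))
    }
    tr <- scene@trees
    for (k in seq_len(nrow(tr))) {
      R <- tr$crown_radius[k]
      near <- abs(x - tr$x[k]) <= R & abs(y - tr$y[k]) <= R
      if (!any(near)) next
      d <- sqrt((x[near] - tr$x[k])^2 + (y[near] - tr$y[k])^2)
      under <- d <= R
      if (!any(under)) next
      idx <- which(near)[under]
      zc <- crownSurface(tr$height[k], R, d[under]) + noise(length(idx))
      z[idx] <- pmax(z[idx], pmax(0, zc))
    }
    pointCloud(x, y, z)
  })
}

#' Render the orthophoto band stack of a scene
#'
#' One grid per configured band at 0.25 m cells, `ceil(area / 0.25)` cells
#' per axis. Pixels whose center lies under a tree crown disc draw from the
#' TREE spectral distribution; every other pixel (ground, roads, buildings,
#' clutter) draws from NOT-TREE.
#'
#' @param scene an [UrbanScene-class]
#' @return an [OrthoStack-class]
#' @export
renderOrtho <- function(scene) {
  cfg <- scene@config
  sp <- cfg$spectral_params
  if (is.null(sp$TREE) || is.null(sp$NOT_TREE))
    stop("spectral_params must define TREE and NOT_TREE")
  cs <- 0.25
  nc <- ceiling(cfg$area_width / cs)
  nr <- ceiling(cfg$area_height / cs)
  origin <- c(0, cfg$area_height)
  cx <- origin[1] + (seq_len(nc) - 0.5) * cs
  cy <- origin[2] - (seq_len(nr) - 0.5) * cs
  treemask <- matrix(FALSE, nr, nc)
  tr <- scene@trees
  for (k in seq_len(nrow(tr))) {
    R <- tr$crown_radius[k]
    jj <- which(abs(cx - tr$x[k]) <= R)
    ii <- which(abs(cy - tr$y[k]) <= R)
    if (!length(jj) || !length(ii)) next
    dx2 <- (cx[jj] - tr$x[k])^2
    dy2 <- (cy[ii] - tr$y[k])^2
    hit <- outer(dy2, dx2, "+") <= R^2
    treemask[ii, jj] <- treemask[ii, jj] | hit
  }
  withSeed(subSeed(cfg$seed, 3L), {
    bands <- list()
    nt <- sum(treemask)
    for (b in names(sp$TREE$mean)) {
      m <- matrix(rnorm(nr * nc, sp$NOT_TREE$mean[[b]], sp$NOT_TREE$sd[[b]]),
                  nr, nc)
      if (nt) m[treemask] <- rnorm(nt, sp$TREE$mean[[b]], sp$TREE$sd[[b]])
      bands[[b]] <- m
    }
    st <- orthoStack(bands, origin = origin, cell_size = cs)
    attr(st, "treemask") <- NULL
    st
  })
}

#' Simulate per-image tree detections at the panorama stations
#'
#' For every station, each true tree within `detection_max_range`, with its
#' stem base inside the image frame and with an unobstructed sight line
#' (blocked iff the station-to-stem segment crosses a building polygon; trees
#' do not occlude each other) yields a stem-base detection with probability
#' `1 - detection_miss_rate`. Pixel coordinates are the exact inverse of the
#' pixel-to-bearing / pixel-to-distance model applied to the true bearing and
#' distance plus configured noise, so with zero noise [locateTrees()]
#' recovers the true positions. Spurious detections (expected
#' `false_detection_rate` per image, Poisson) point at ground targets more
#' than 5 m from every true tree.
#'
#' @param scene an [UrbanScene-class]
#' @return data.frame `station_id, kind, u, v, confidence, truth_id`
#'   (`truth_id` is `NA` for spurious detections; it is simulator ground
#'   truth and is never consumed by the pipeline).
#' @export
simulateDetections <- function(scene) {
  cfg <- scene@config
  st <- scene@stations
  if (!nrow(st)) stop("scene has no stations")
  tr <- scene@trees
  withSeed(subSeed(cfg$seed, 4L), {
    rows <- vector("list", nrow(st))
    for (s in seq_len(nrow(st))) {
      stn <- st[s, ]
      out <- list()
      for (k in seq_len(nrow(tr))) {
        dx <- tr$x[k] - stn$x; dy <- tr$y[k] - stn$y
        d <- sqrt(dx^2 + dy^2)
        if (d < 0.5 || d > cfg$detection_max_range) next
        if (occludedByBuildings(c(stn$x, stn$y), c(tr$x[k], tr$y[k]),
                                scene@buildings)) next
        if (runif(1) < cfg$detection_miss_rate) next
        brg <- wrapDeg360(rad2deg(atan2(dx, dy)) + rnorm(1, 0, cfg$bearing_noise_sd))
        dd <- d + rnorm(1, 0, cfg$distance_noise_sd)
        if (dd <= 0.1) next
        u <- bearingToPixel(stn, brg, model = cfg$pixel_model)
        v <- distanceToPixel(stn, dd)
        if (is.na(u) || is.na(v)) next
        out[[length(out) + 1]] <- data.frame(
          station_id = stn$id, kind = "stem", u = u, v = v,
          confidence = 1, truth_id = tr$id[k], stringsAsFactors = FALSE)
      }
      nfp <- rpois(1, cfg$false_detection_rate)
      fp <- 0; tries <- 0
      while (fp < nfp && tries < 100 * max(1, nfp)) {
        tries <- tries + 1
        qx <- runif(1, 0, cfg$area_width); qy <- runif(1, 0, cfg$area_height)
        if (nrow(tr) && min(sqrt((tr$x - qx)^2 + (tr$y - qy)^2)) <= 5) next
        dx <- qx - stn$x; dy <- qy - stn$y
        d <- sqrt(dx^2 + dy^2)
        if (d < 0.5) next
        u <- bearingToPixel(stn, wrapDeg360(rad2deg(atan2(dx, dy))),
                            model = cfg$pixel_model)
        v <- distanceToPixel(stn, d)
        if (is.na(u) || is.na(v)) next
        fp <- fp + 1
        out[[length(out) + 1]] <- data.frame(
          station_id = stn$id, kind = "stem", u = u, v = v,
          confidence = stats::runif(1, 0.5, 1), truth_id = NA_character_,
          stringsAsFactors = FALSE)
      }
      rows[[s]] <- if (length(out)) do.call(rbind, out) else NULL
    }
    res <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(res)) emptyDetections() else res
  })
}

occludedByBuildings <- function(p1, p2, buildings) {
  for (poly in buildings)
    if (segmentIntersectsPolygon(p1, p2, poly)) return(TRUE)
  FALSE
}

#' Sample labeled spectral ground-truth points
#'
#' Draws `n` labeled points for classifier training: TREE points well inside
#' crown discs (at least 0.6 m from the crown edge where the crown allows) and
#' NOT-TREE points at least 0.6 m outside every crown, both kept 0.6 m inside
#' the scene bounds so a 0.5 m zonal buffer stays on-raster and spectrally
#' pure.
#'
#' @param scene an [UrbanScene-class]
#' @param n total number of points (split evenly between classes)
#' @return data.frame `x, y, class` with `class` in `TREE, NOT_TREE`
#' @export
sampleTruthPoints <- function(scene, n = scene@config$n_truth_samples) {
  cfg <- scene@config
  tr <- scene@trees
  if (!nrow(tr)) stop("scene has no trees to sample TREE points from")
  w <- cfg$area_width; h <- cfg$area_height
  withSeed(subSeed(cfg$seed, 5L), {
    nt <- ceiling(n / 2); nn <- n - nt
    ks <- sample.int(nrow(tr), nt, replace = TRUE)
    rmax <- pmax(0.05, tr$crown_radius[ks] - 0.6)
    rr <- sqrt(runif(nt)) * rmax
    th <- runif(nt, 0, 2 * pi)
    tx <- pmin(pmax(tr$x[ks] + rr * sin(th), 0.6), w - 0.6)
    ty <- pmin(pmax(tr$y[ks] + rr * cos(th), 0.6), h - 0.6)
    ox <- oy <- numeric(0)
    while (length(ox) < nn) {
      m <- (nn - length(ox)) * 2 + 10
      qx <- runif(m, 0.6, w - 0.6); qy <- runif(m, 0.6, h - 0.6)
      clear <- rep(TRUE, m)
      for (k in seq_len(nrow(tr))) {
        d <- sqrt((qx - tr$x[k])^2 + (qy - tr$y[k])^2)
        clear <- clear & d > tr$crown_radius[k] + 0.6
      }
      ox <- c(ox, qx[clear]); oy <- c(oy, qy[clear])
    }
    data.frame(x = c(tx, ox[seq_len(nn)]), y = c(ty, oy[seq_len(nn)]),
               class = c(rep("TREE", nt), rep("NOT_TREE", nn)),
               stringsAsFactors = FALSE)
  })
}

#' Generate a complete synthetic scene
#'
#' [generateScene()] plus point cloud, ortho stack and per-image detections
#' in one call.
#'
#' @param config a [sceneConfig()]
#' @return an [UrbanScene-class] with all slots filled.
#' @export
simulateScene <- function(config) {
  scene <- generateScene(config)
  scene@cloud <- renderPointCloud(scene)
  scene@ortho <- renderOrtho(scene)
  scene@detections <- simulateDetections(scene)
  scene
}

#' @rdname UrbanScene-class
#' @export
setMethod("sceneTrees", "UrbanScene", function(x) x@trees)
#' @rdname UrbanScene-class
#' @export
setMethod("sceneStations", "UrbanScene", function(x) x@stations)
#' @rdname UrbanScene-class
#' @export
setMethod("sceneBuildings", "UrbanScene", function(x) x@buildings)
#' @rdname UrbanScene-class
#' @export
setMethod("sceneDetections", "UrbanScene", function(x) x@detections)
#' @rdname UrbanScene-class
#' @export
setMethod("sceneCloud", "UrbanScene", function(x) x@cloud)
#' @rdname UrbanScene-class
#' @export
setMethod("sceneOrtho", "UrbanScene", function(x) x@ortho)
#' @rdname UrbanScene-class
#' @export
setMethod("sceneClutter", "UrbanScene", function(x) x@clutter)

setMethod("show", "UrbanScene", function(object) {
  cat("UrbanScene:", object@config$area_width, "x", object@config$area_height,
      "m, seed", object@config$seed, "\n")
  cat("  trees:", nrow(object@trees),
      sprintf("(%d street, %d park)", sum(object@trees$zone == "street"),
              sum(object@trees$zone == "park")), "\n")
  cat("  buildings:", length(object@buildings),
      " clutter:", nrow(object@clutter),
      " stations:", nrow(object@stations), "\n")
  cat("  cloud:", nrow(object@cloud@points), "points;  detections:",
      nrow(object@detections), "\n")
})

# distance from points to the nearest building rectangle (0 when inside)
distToRects <- function(px, py, rects) {
  if (!length(rects)) return(rep(Inf, length(px)))
  d <- rep(Inf, length(px))
  for (r in rects) {
    dx <- pmax(0, r[1] - px, px - r[3])
    dy <- pmax(0, r[2] - py, py - r[4])
    d <- pmin(d, sqrt(dx^2 + dy^2))
  }
  d
}
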