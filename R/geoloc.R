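# Stage 1A: geolocate trees from per-image stem-base detections using the
# station's heading/pitch/FOV, and stage 2A: verify candidates against the
# three nearest stations. A "station" is one row of the stations table (or an
# equivalent named list): id, x, y, heading, pitch, hfov, vfov, img_width,
# img_height, camera_height.

#' Pixel column to compass bearing
#'
#' Perspective (rectilinear) model:
#' `bearing = heading + atan((2u/W - 1) * tan(hfov/2))`; equirectangular
#' model: `bearing = heading + (u/W - 1/2) * hfov`. Result in `[0, 360)`
#' degrees clockwise from north.
#'
#' @param station a station row/list (see above)
#' @param u pixel column from the image left edge (0-based, `0 <= u < W`)
#' @param model `"perspective"` or `"equirect"`
#' @return bearing in degrees, vectorized over `u`
#' @export
pixelToBearing <- function(station, u, model = c("perspective", "equirect")) {
  model <- match.arg(model)
  W <- station$img_width
  if (any(u < 0 | u >= W)) stop("pixel column outside the image")
  if (model == "perspective") {
    if (station$hfov >= 180) stop("perspective model requires hfov < 180")
    off <- rad2deg(atan((2 * u / W - 1) * tan(deg2rad(station$hfov / 2))))
  } else {
    off <- (u / W - 0.5) * station$hfov
  }
  wrapDeg360(station$heading + off)
}

#' Pixel row of a stem base to ground distance
#'
#' Flat-ground depression-angle model with known camera height: the
#' depression angle of the stem base is
#' `delta = -pitch + atan((2v/H - 1) * tan(vfov/2))` (v measured down from
#' the top row, perspective vertical model) and
#' `distance = camera_height / tan(delta)`. A stem base at or above the
#' horizon row (`delta <= 0`) carries no distance information and is an
#' error.
#'
#' @param station a station row/list
#' @param v pixel row from the image top (0-based, `0 <= v < H`)
#' @return distance in meters, vectorized over `v`
#' @export
pixelToDistance <- function(station, v) {
  H <- station$img_height
  if (any(v < 0 | v >= H)) stop("pixel row outside the image")
  delta <- -station$pitch +
    rad2deg(atan((2 * v / H - 1) * tan(deg2rad(station$vfov / 2))))
  if (any(delta <= 0))
    stop("stem base at or above the horizon: no distance estimate")
  station$camera_height / tan(deg2rad(delta))
}

# exact inverses, used by the detection simulator; NA when out of frame
bearingToPixel <- function(station, bearing, model = c("perspective", "equirect")) {
  model <- match.arg(model)
  W <- station$img_width
  db <- wrapDeg180(bearing - station$heading)
  if (model == "perspective") {
    if (abs(db) >= station$hfov / 2) return(NA_real_)
    u <- W / 2 * (1 + tan(deg2rad(db)) / tan(deg2rad(station$hfov / 2)))
  } else {
    if (db < -station$hfov / 2 || db >= station$hfov / 2) return(NA_real_)
    u <- W * (db / station$hfov + 0.5)
  }
  if (u < 0 || u >= W) NA_real_ else u
}

distanceToPixel <- function(station, distance) {
  if (distance <= 0) return(NA_real_)
  H <- station$img_height
  delta <- rad2deg(atan(station$camera_height / distance))
  t <- tan(deg2rad(delta + station$pitch)) / tan(deg2rad(station$vfov / 2))
  if (!is.finite(t) || t <= 0 || t >= 1) return(NA_real_)
  v <- H / 2 * (1 + t)
  if (v <= H / 2 || v >= H) NA_real_ else v
}

#' Project a bearing/distance observation to planar coordinates
#'
#' `x = xs + d sin(bearing)`, `y = ys + d cos(bearing)` with the bearing in
#' degrees clockwise from north.
#'
#' @param station a station row/list
#' @param bearing degrees clockwise from north
#' @param distance meters, > 0
#' @return numeric c(x, y) (or a 2-column matrix when vectorized)
#' @export
projectObservation <- function(station, bearing, distance) {
  if (any(distance <= 0)) stop("distance must be positive")
  b <- deg2rad(bearing)
  x <- station$x + distance * sin(b)
  y <- station$y + distance * cos(b)
  if (length(x) == 1) c(x, y) else cbind(x = x, y = y)
}

#' Geolocate one candidate tree per stem detection (stage 1A)
#'
#' Applies [pixelToBearing()], [pixelToDistance()] and
#' [projectObservation()] to every stem detection. Detections whose stem base
#' is at or above the horizon are dropped and counted (attribute
#' `n_dropped`). Duplicates from the same tree seen in several images are NOT
#' resolved here; that is [mergeCandidates()]'s job.
#'
#' @param stations stations table
#' @param detections detections table (`station_id, kind, u, v, ...`)
#' @param model pixel model passed to [pixelToBearing()]
#' @return candidate data.frame with `source = "GSV"` and an `n_dropped`
#'   attribute
#' @export
locateTrees <- function(stations, detections,
                        model = c("perspective", "equirect")) {
  model <- match.arg(model)
  det <- detections[detections$kind == "stem", , drop = FALSE]
  if (!nrow(det))
    return(structure(treeCandidates(), n_dropped = 0L))
  if (!all(det$station_id %in% stations$id))
    stop("detection references an unknown station id")
  xs <- ys <- numeric(nrow(det))
  ok <- logical(nrow(det))
  for (k in seq_len(nrow(det))) {
    stn <- stations[stations$id == det$station_id[k], ]
    b <- pixelToBearing(stn, det$u[k], model)
    d <- tryCatch(pixelToDistance(stn, det$v[k]), error = function(e) NA_real_)
    if (is.na(d)) next
    p <- projectObservation(stn, b, d)
    xs[k] <- p[1]; ys[k] <- p[2]; ok[k] <- TRUE
  }
  out <- treeCandidates(id = sprintf("GSV%05d", seq_len(sum(ok))),
                        x = xs[ok], y = ys[ok], height = NA_real_,
                        source = "GSV")
  if ("truth_id" %in% names(det)) out$truth_id <- det$truth_id[ok]
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Verification parameters for the nearest-images check (stage 2A)
#'
#' @param k_images number of nearest stations checked (>= 2; default 3)
#' @param consistency_distance maximum pairwise distance among the k
#'   re-located positions (m; default 4)
#' @param require_all keep a candidate only if it is re-detected in all k
#'   images (default TRUE, the strict reading)
#' @return a `verifyParams` list
#' @export
verifyParams <- function(k_images = 3, consistency_distance = 4,
                         require_all = TRUE) {
  if (k_images < 2) stop("k_images must be >= 2")
  if (consistency_distance <= 0) stop("consistency_distance must be > 0")
  p <- list(k_images = k_images, consistency_distance = consistency_distance,
            require_all = require_all)
  class(p) <- c("verifyParams", "list")
  p
}

#' Verify candidates against their nearest panorama stations (stage 2A)
#'
#' For each candidate, take the `k_images` nearest stations (planar distance,
#' ties by station id), ask the `detector` for a re-detection of the
#' candidate in each, and keep the candidate iff it is re-detected in all k
#' images (when `require_all`) and all pairwise distances among the k
#' re-located positions are below `consistency_distance`. Kept candidates are
#' repositioned at the arithmetic centroid of the k positions and tagged
#' `source = "filtered"`.
#'
#' @param candidates candidate data.frame
#' @param stations stations table
#' @param detector `function(station, candidate)` returning a position
#'   `c(x, y)` (a consistent detection in that station's image) or `NULL`;
#'   see [makeDetectionProvider()]
#' @param params a [verifyParams()]
#' @return filtered candidate data.frame (ids preserved, positions moved to
#'   the centroid)
#' @export
verifyCandidates <- function(candidates, stations, detector,
                             params = verifyParams()) {
  if (nrow(stations) < params$k_images)
    stop("fewer than k_images stations available")
  if (!nrow(candidates)) return(candidates)
  keep <- logical(nrow(candidates))
  nx <- ny <- numeric(nrow(candidates))
  for (k in seq_len(nrow(candidates))) {
    cand <- candidates[k, ]
    d <- sqrt((stations$x - cand$x)^2 + (stations$y - cand$y)^2)
    ord <- order(d, stations$id)[seq_len(params$k_images)]
    pos <- list()
    for (s in ord) {
      p <- detector(stations[s, ], cand)
      if (is.null(p) && params$require_all) { pos <- NULL; break }
      if (!is.null(p)) pos[[length(pos) + 1]] <- p
    }
    if (is.null(pos) || length(pos) < 2) next
    m <- do.call(rbind, pos)
    pd <- as.matrix(stats::dist(m))
    if (max(pd) >= params$consistency_distance) next
    keep[k] <- TRUE
    nx[k] <- mean(m[, 1]); ny[k] <- mean(m[, 2])
  }
  out <- candidates[keep, , drop = FALSE]
  out$x <- nx[keep]; out$y <- ny[keep]
  out$source <- rep_len("filtered", nrow(out))
  rownames(out) <- NULL
  out
}

#' Build a detection provider over a simulated detections table
#'
#' Satisfies the `detector` contract of [verifyCandidates()]: given a station
#' and a candidate, re-project all of that station's stem detections to
#' planar positions and return the one nearest to the candidate if it lies
#' within `max_offset` meters, else `NULL`. A real detector (e.g. a CNN run
#' on demand) can implement the same contract.
#'
#' @param stations stations table
#' @param detections detections table
#' @param model pixel model
#' @param max_offset association radius in meters (default 4, matching the
#'   consistency distance)
#' @return `function(station, candidate) -> c(x, y) | NULL`
#' @export
makeDetectionProvider <- function(stations, detections,
                                  model = c("perspective", "equirect"),
                                  max_offset = 4) {
  model <- match.arg(model)
  # pre-project every detection once
  located <- locateTrees(stations, detections, model)
  sid <- detections$station_id[detections$kind == "stem"]
  # locateTrees drops horizon failures; rebuild the station index to match
  keep <- logical(length(sid))
  i <- 0
  for (k in seq_along(sid)) {
    stn <- stations[stations$id == sid[k], ]
    d <- tryCatch(pixelToDistance(stn, detections$v[detections$kind == "stem"][k]),
                  error = function(e) NA_real_)
    keep[k] <- !is.na(d)
  }
  sid <- sid[keep]
  function(station, candidate) {
    idx <- which(sid == station$id)
    if (!length(idx)) return(NULL)
    dx <- located$x[idx] - candidate$x
    dy <- located$y[idx] - candidate$y
    d <- sqrt(dx^2 + dy^2)
    j <- which.min(d)
    if (d[j] > max_offset) return(NULL)
    c(located$x[idx[j]], located$y[idx[j]])
  }
}
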