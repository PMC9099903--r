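# Planar geometry primitives and small numeric helpers used across modules.
# Boundary convention: polygon boundaries count as inside (clipping removes
# cell centers ON a building outline as well as strictly interior ones).

# Vectorized point-in-polygon (even-odd ray casting) with inclusive boundary.
# poly: two-column matrix of vertices, not necessarily closed.
pointInPolygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- rep(FALSE, length(px))
  onedge <- rep(FALSE, length(px))
  eps <- 1e-12
  for (k in seq_len(n)) {
    x1 <- xs[k]; y1 <- ys[k]; x2 <- xe[k]; y2 <- ye[k]
    # boundary test: point collinear with and between segment endpoints
    cross <- (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1)
    within <- pmin(x1, x2) - eps <= px & px <= pmax(x1, x2) + eps &
              pmin(y1, y2) - eps <= py & py <= pmax(y1, y2) + eps
    onedge <- onedge | (abs(cross) <= eps * (1 + abs(px) + abs(py)) & within)
    # ray casting (horizontal ray to +x), half-open in y to avoid double count
    crosses <- ((y1 > py) != (y2 > py)) &
               (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
  }
  inside | onedge
}

# TRUE if segment p1-p2 crosses (or touches) polygon `poly`, or if either
# endpoint lies inside it. Used for building occlusion of sight lines.
segmentIntersectsPolygon <- function(p1, p2, poly) {
  if (any(pointInPolygon(c(p1[1], p2[1]), c(p1[2], p2[2]), poly))) return(TRUE)
  n <- nrow(poly)
  for (k in seq_len(n)) {
    q1 <- poly[k, ]; q2 <- poly[if (k == n) 1 else k + 1, ]
    if (segmentsIntersect(p1, p2, q1, q2)) return(TRUE)
  }
  FALSE
}

orient <- function(a, b, c) {
  v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  if (abs(v) < 1e-12) 0 else sign(v)
}

onSegment <- function(a, b, p) {
  min(a[1], b[1]) - 1e-12 <= p[1] && p[1] <= max(a[1], b[1]) + 1e-12 &&
  min(a[2], b[2]) - 1e-12 <= p[2] && p[2] <= max(a[2], b[2]) + 1e-12
}

segmentsIntersect <- function(p1, p2, q1, q2) {
  o1 <- orient(p1, p2, q1); o2 <- orient(p1, p2, q2)
  o3 <- orient(q1, q2, p1); o4 <- orient(q1, q2, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && onSegment(p1, p2, q1)) || (o2 == 0 && onSegment(p1, p2, q2)) ||
  (o3 == 0 && onSegment(q1, q2, p1)) || (o4 == 0 && onSegment(q1, q2, p2))
}

# Axis-aligned rectangle c(xmin, ymin, xmax, ymax) -> polygon matrix.
rectToPolygon <- function(r) {
  cbind(c(r[1], r[3], r[3], r[1]), c(r[2], r[2], r[4], r[4]))
}

# wrap an angle in degrees to [-180, 180)
wrapDeg180 <- function(a) ((a + 180) %% 360) - 180

# wrap to [0, 360)
wrapDeg360 <- function(a) a %% 360

deg2rad <- function(d) d * pi / 180
rad2deg <- function(r) r * 180 / pi

# round half away from zero (base round() rounds half to even)
roundHalfUp <- function(x, digits = 2) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Run expr with a temporary RNG state seeded at `seed`; restores the caller's
# stream so generator sub-steps are independently reproducible.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% .Machine$integer.max))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

# Small deterministic sub-seed derivation (keeps results < 2^31).
subSeed <- function(seed, k) as.integer((as.numeric(seed) * 97 + k * 1009) %% 2147483647L)
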