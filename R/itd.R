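#' Variable-window treetop detection parameters
#'
#' The search-window radius grows linearly with candidate height:
#' `radius(h) = win_a * h + win_b` meters, evaluated at the candidate cell's
#' own (smoothed) height and optionally capped at `max_win_diameter / 2`.
#' Defaults follow the reference parameterization for urban trees:
#' `min_height = 2` m, `winFun = 0.12 h + 0.5`, no diameter cap, queen
#' minimum neighborhood.
#'
#' @param min_height minimum treetop height (m)
#' @param win_a,win_b slope (unitless) and intercept (m) of the window radius
#' @param max_win_diameter optional cap on the window diameter (m), `NULL` =
#'   uncapped
#' @param neighborhood `"queen"` (8-connected) or `"rook"` (4-connected):
#'   the adjacent cells always included in the window even when the radius is
#'   smaller than one cell
#' @return an `itdParams` list
#' @export
itdParams <- function(min_height = 2, win_a = 0.12, win_b = 0.5,
                      max_win_diameter = NULL,
                      neighborhood = c("queen", "rook")) {
  if (min_height < 0) stop("min_height must be >= 0")
  if (win_a * min_height + win_b <= 0)
    stop("window radius must be positive for all h >= min_height")
  p <- list(min_height = min_height, win_a = win_a, win_b = win_b,
            max_win_diameter = max_win_diameter,
            neighborhood = match.arg(neighborhood))
  class(p) <- c("itdParams", "list")
  p
}

#' Window radius as a function of height
#'
#' `win_a * h + win_b`, capped at `max_win_diameter / 2` when set. At the
#' default parameters: 0.5 m at h = 0, 0.74 m at the 2 m minimum height,
#' 2.0 m for a 12.5 m tree.
#'
#' @param h height(s) in meters
#' @param params an [itdParams()]
#' @return radius in meters (vectorized)
#' @export
windowRadius <- function(h, params = itdParams()) {
  r <- params$win_a * h + params$win_b
  if (!is.null(params$max_win_diameter))
    r <- pmin(r, params$max_win_diameter / 2)
  r
}

#' Detect treetops as variable-window local maxima
#'
#' A cell is a treetop iff (a) its value is at least `min_height`, (b) no
#' valid cell whose center lies within `windowRadius(value)` of its center
#' has a larger value, and (c) among equal-valued cells within that window it
#' comes first in row-major order (deterministic plateau tie-break). Nodata
#' cells inside the window are ignored, so treetops at building edges remain
#' detectable. Circle membership is by cell-center distance <= radius; the
#' queen (or rook) adjacent cells are always part of the window.
#'
#' @param chm a [RasterGrid-class] (normally smoothed and building-clipped)
#' @param params an [itdParams()]
#' @return candidate data.frame (see [treeCandidates()]) with cell-center
#'   coordinates, the CHM value as height, and `source = "ALS"`.
#' @export
detectTreetops <- function(chm, params = itdParams()) {
  v <- chm@values
  nr <- nrow(v); nc <- ncol(v)
  cs <- chm@cellSize
  cand <- which(!is.na(v) & v >= params$min_height)
  if (!length(cand)) return(treeCandidates())
  # cheap prefilter: a treetop must be >= its always-included adjacent cells
  keep <- vapply(cand, function(lin) {
    i <- ((lin - 1L) %% nr) + 1L; j <- ((lin - 1L) %/% nr) + 1L
    val <- v[i, j]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      if (params$neighborhood == "rook" && di != 0 && dj != 0) next
      ii <- i + di; jj <- j + dj
      if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
      if (!is.na(v[ii, jj]) && v[ii, jj] > val) return(FALSE)
    }
    TRUE
  }, logical(1))
  cand <- cand[keep]
  hits <- logical(length(cand))
  for (k in seq_along(cand)) {
    lin <- cand[k]
    i <- ((lin - 1L) %% nr) + 1L; j <- ((lin - 1L) %/% nr) + 1L
    val <- v[i, j]
    r <- windowRadius(val, params)
    rc <- ceiling(r / cs)
    ii <- max(1, i - rc - 1):min(nr, i + rc + 1)
    jj <- max(1, j - rc - 1):min(nc, j + rc + 1)
    sub <- v[ii, jj, drop = FALSE]
    d2 <- outer((ii - i)^2, (jj - j)^2, "+") * cs^2
    inwin <- d2 <= r^2 + 1e-12
    # minimum neighborhood always included
    adj <- if (params$neighborhood == "queen")
      outer(abs(ii - i) <= 1, abs(jj - j) <= 1, "&")
    else
      outer(abs(ii - i), abs(jj - j), "+") <= 1
    inwin <- inwin | adj
    inwin[ii == i, jj == j] <- FALSE  # the cell itself
    vals <- sub[inwin & !is.na(sub)]
    if (length(vals) && max(vals) > val) next
    if (length(vals) && any(vals == val)) {
      # row-major-first tie-break among equal-valued cells in the window
      eq <- inwin & !is.na(sub) & sub == val
      eqi <- ii[row(sub)[eq]]; eqj <- jj[col(sub)[eq]]
      self_rm <- (i - 1) * nc + (j - 1)
      if (any((eqi - 1) * nc + (eqj - 1) < self_rm)) next
    }
    hits[k] <- TRUE
  }
  cand <- cand[hits]
  i <- ((cand - 1L) %% nr) + 1L; j <- ((cand - 1L) %/% nr) + 1L
  cc <- cellCenters(chm)
  ord <- order(i, j)  # row-major output order
  i <- i[ord]; j <- j[ord]
  treeCandidates(id = sprintf("ALS%05d", seq_along(i)),
                 x = cc$x[j], y = cc$y[i],
                 height = v[cbind(i, j)], source = "ALS")
}
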