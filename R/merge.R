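#' Merging parameters
#'
#' Candidates closer than `merge_distance` are fused: circular buffers of
#' radius `merge_distance / 2` intersect exactly when two centers are less
#' than `merge_distance` apart (tangency at exactly that distance does not
#' merge), and connected components of intersecting buffers collapse to one
#' candidate.
#'
#' @param merge_distance meters (default 4)
#' @param position_rule `"point_centroid"` (mean of member positions,
#'   default) or `"polygon_centroid"` (area centroid of the buffer union,
#'   computed by deterministic grid integration at step `merge_distance/50`)
#' @param iterate merge again until no two output centroids are closer than
#'   `merge_distance` (chains can create new proximities); `FALSE` gives the
#'   strict single-pass variant
#' @return a `mergeParams` list
#' @export
mergeParams <- function(merge_distance = 4,
                        position_rule = c("point_centroid", "polygon_centroid"),
                        iterate = TRUE) {
  if (merge_distance <= 0) stop("merge_distance must be > 0")
  p <- list(merge_distance = merge_distance,
            position_rule = match.arg(position_rule), iterate = iterate)
  class(p) <- c("mergeParams", "list")
  p
}

#' Merge candidate trees by buffer union
#'
#' Builds circular buffers of radius `merge_distance/2` around every
#' candidate; connected components of buffer intersection (equivalently, the
#' transitive closure of the "distance < merge_distance" graph) each collapse
#' to one candidate at the component centroid. The merged height is the
#' maximum member height (when any is present), the new id is derived
#' deterministically from the sorted member ids, and `source` becomes
#' `"merged"`. By default merging is repeated until no two output centroids
#' are closer than `merge_distance` (fixed point, at most n passes); the
#' number of passes is recorded in attribute `n_passes` and component
#' membership of the first pass in attribute `members`.
#'
#' @param candidates candidate data.frame
#' @param params a [mergeParams()]
#' @return merged candidate data.frame
#' @export
mergeCandidates <- function(candidates, params = mergeParams()) {
  validateCandidates(candidates)
  if (nrow(candidates) <= 1) {
    out <- candidates
    if (nrow(out)) out$source <- "merged"
    attr(out, "n_passes") <- 1L
    attr(out, "members") <- if (nrow(out))
      data.frame(component = out$id, member = out$id) else
      data.frame(component = character(), member = character())
    return(out)
  }
  cur <- candidates
  members <- NULL
  passes <- 0L
  repeat {
    passes <- passes + 1L
    comp <- mergeComponents(cur$x, cur$y, params$merge_distance)
    if (is.null(members))
      members <- data.frame(component = NA_character_, member = cur$id,
                            comp = comp, stringsAsFactors = FALSE)
    nxt <- collapseComponents(cur, comp, params)
    if (passes == 1L) {
      key <- vapply(split(cur$id, comp), function(ids)
        paste(sort(ids), collapse = "+"), character(1))
      members$component <- key[as.character(comp)]
      members$comp <- NULL
    }
    done <- nrow(nxt) == nrow(cur) || !params$iterate
    cur <- nxt
    if (done) break
    if (passes > nrow(candidates)) break  # safety; cannot trigger
  }
  attr(cur, "n_passes") <- passes
  attr(cur, "members") <- members
  cur
}

# union-find over the "closer than threshold" graph, grid-bucketed
mergeComponents <- function(x, y, threshold) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) { parent[a] <<- parent[parent[a]]; a <- parent[a] }; a }
  union <- function(a, b) { ra <- find(a); rb <- find(b); if (ra != rb) parent[ra] <<- rb }
  bx <- floor(x / threshold); by <- floor(y / threshold)
  key <- paste(bx, by)
  buckets <- split(seq_len(n), key)
  lookup <- new.env(parent = emptyenv())
  for (k in names(buckets)) assign(k, buckets[[k]], envir = lookup)
  for (a in seq_len(n)) {
    for (dx in -1:1) for (dy in -1:1) {
      k <- paste(bx[a] + dx, by[a] + dy)
      if (!exists(k, envir = lookup, inherits = FALSE)) next
      for (b in get(k, envir = lookup)) {
        if (b <= a) next
        if ((x[a] - x[b])^2 + (y[a] - y[b])^2 < threshold^2) union(a, b)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

collapseComponents <- function(cands, comp, params) {
  groups <- split(seq_len(nrow(cands)), comp)
  out <- lapply(groups, function(idx) {
    sub <- cands[idx, , drop = FALSE]
    if (params$position_rule == "polygon_centroid" && nrow(sub) > 1) {
      ctr <- bufferUnionCentroid(sub$x, sub$y, params$merge_distance / 2,
                                 step = params$merge_distance / 50)
    } else {
      ctr <- c(mean(sub$x), mean(sub$y))
    }
    hh <- sub$height[!is.na(sub$height)]
    data.frame(id = paste(sort(sub$id), collapse = "+"),
               x = ctr[1], y = ctr[2],
               height = if (length(hh)) max(hh) else NA_real_,
               source = "merged", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# area centroid of a union of equal circles by grid integration
bufferUnionCentroid <- function(x, y, radius, step) {
  gx <- seq(min(x) - radius, max(x) + radius, by = step)
  gy <- seq(min(y) - radius, max(y) + radius, by = step)
  px <- rep(gx, times = length(gy))
  py <- rep(gy, each = length(gx))
  covered <- rep(FALSE, length(px))
  for (k in seq_along(x))
    covered <- covered | ((px - x[k])^2 + (py - y[k])^2 <= radius^2)
  c(mean(px[covered]), mean(py[covered]))
}
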