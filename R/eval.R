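#' Evaluation parameters
#'
#' @param match_distance maximum candidate-to-truth distance for a match
#'   (strict `<`; meters, default 5)
#' @return an `evalParams` list
#' @export
evalParams <- function(match_distance = 5) {
  if (match_distance <= 0) stop("match_distance must be > 0")
  p <- list(match_distance = match_distance)
  class(p) <- c("evalParams", "list")
  p
}

#' Match candidate trees to ground truth
#'
#' Candidate-side matching criteria, applied literally (no global
#' assignment): for each candidate `c` with nearest truth point `g`, `c` is a
#' true positive iff `dist(c, g) < match_distance` AND `c` is the candidate
#' nearest to `g` (distance ties broken by candidate id, ascending);
#' otherwise `c` is a false positive — either it is too far from every truth
#' point, or another candidate closer to `g` claims the match. A truth point
#' is a false negative iff NO candidate lies within `match_distance` of it.
#' A truth point that has candidates in range but is not any candidate's
#' winning match is neither matched nor a false negative, so `TP + FN` may be
#' smaller than the number of truth points; `TP + FP` always equals the
#' number of candidates. Both invariants are asserted on every call.
#'
#' @param candidates candidate data.frame (`id, x, y, ...`)
#' @param truth data.frame of ground-truth trees (`id, x, y, ...`)
#' @param params an [evalParams()]
#' @return a `matchResult` list: `TP`, `FP`, `FN` counts, `tp_pairs`
#'   (candidate id, truth id, distance), `fp_ids`, `fn_ids`
#' @export
matchCandidates <- function(candidates, truth, params = evalParams()) {
  nc <- nrow(candidates); nt <- nrow(truth)
  if (nc == 0 || nt == 0) {
    res <- list(TP = 0L, FP = nc, FN = nt,
                tp_pairs = data.frame(candidate_id = character(),
                                      truth_id = character(),
                                      distance = numeric()),
                fp_ids = if (nc) candidates$id else character(),
                fn_ids = if (nt) truth$id else character())
    class(res) <- c("matchResult", "list")
    return(res)
  }
  dmat <- outer(candidates$x, truth$x, "-")^2 + outer(candidates$y, truth$y, "-")^2
  dmat <- sqrt(dmat)  # nc x nt
  # nearest truth per candidate (row minima); generic ties assumed
  g_of_c <- apply(dmat, 1, which.min)
  d_of_c <- dmat[cbind(seq_len(nc), g_of_c)]
  # nearest candidate per truth, distance ties by candidate id ascending
  ord <- order(candidates$id)
  id_rank <- match(seq_len(nc), ord)
  c_of_g <- apply(dmat, 2, function(col) {
    tied <- which(col == min(col))
    tied[which.min(id_rank[tied])]
  })
  is_tp <- d_of_c < params$match_distance & c_of_g[g_of_c] == seq_len(nc)
  fn <- apply(dmat, 2, min) >= params$match_distance
  res <- list(
    TP = sum(is_tp), FP = sum(!is_tp), FN = sum(fn),
    tp_pairs = data.frame(candidate_id = candidates$id[is_tp],
                          truth_id = truth$id[g_of_c[is_tp]],
                          distance = d_of_c[is_tp],
                          stringsAsFactors = FALSE),
    fp_ids = candidates$id[!is_tp],
    fn_ids = truth$id[fn])
  class(res) <- c("matchResult", "list")
  stopifnot(res$TP + res$FP == nc, res$TP + res$FN <= nt,
            all(res$tp_pairs$distance < params$match_distance))
  res
}

#' @export
print.matchResult <- function(x, ...) {
  cat("matchResult: TP", x$TP, " FP", x$FP, " FN", x$FN, "\n")
  invisible(x)
}

#' Precision, recall and F1 from match counts
#'
#' `p = 100 TP/(TP+FP)`, `r = 100 TP/(TP+FN)`, `F1 = 2pr/(p+r)` computed from
#' the unrounded p and r (rounding first loses the second decimal in some
#' published rows), then reported rounded half-away-from-zero to 2 decimals.
#' Zero denominators give 0 by convention.
#'
#' @param x a `matchResult` from [matchCandidates()], or the TP count
#' @param fp,fn FP and FN counts when `x` is given as a count
#' @return a `treeMetrics` data.frame: `TP, FP, FN, p, r, F1` (percent,
#'   2 decimals) with unrounded values in attribute `unrounded`
#' @export
computeMetrics <- function(x, fp = NULL, fn = NULL) {
  if (inherits(x, "matchResult")) {
    tp <- x$TP; fp <- x$FP; fn <- x$FN
  } else {
    tp <- x
    if (is.null(fp) || is.null(fn)) stop("fp and fn counts required")
  }
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  out <- data.frame(TP = tp, FP = fp, FN = fn,
                    p = roundHalfUp(p, 2), r = roundHalfUp(r, 2),
                    F1 = roundHalfUp(f1, 2))
  class(out) <- c("treeMetrics", "data.frame")
  attr(out, "unrounded") <- c(p = p, r = r, F1 = f1)
  out
}

#' Pool match results across zones
#'
#' Sums TP/FP/FN over zones, then computes the metrics from the pooled
#' counts (not the mean of per-zone percentages).
#'
#' @param results list of `matchResult` objects (or a data.frame with TP, FP,
#'   FN columns)
#' @return pooled `treeMetrics`
#' @export
pooledMetrics <- function(results) {
  if (is.data.frame(results)) {
    tp <- sum(results$TP); fp <- sum(results$FP); fn <- sum(results$FN)
  } else {
    if (!length(results)) stop("at least one zone required")
    tp <- sum(vapply(results, `[[`, numeric(1), "TP"))
    fp <- sum(vapply(results, `[[`, numeric(1), "FP"))
    fn <- sum(vapply(results, `[[`, numeric(1), "FN"))
  }
  computeMetrics(tp, fp, fn)
}
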