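# Independent brute-force oracles. These re-state the definitions directly
# with plain loops and are kept free of any code shared with the package
# internals they check.

# Variable-window local-maxima treetops, by direct enumeration: for every
# cell, scan the bounding box of its window and apply the definition
# (value >= min_height; no larger value within radius or in the always-included
# adjacency; equal values only at later row-major positions).
itdOracle <- function(v, cell_size, min_height = 2, win_a = 0.12,
                      win_b = 0.5, neighborhood = "queen") {
  nr <- nrow(v); nc <- ncol(v)
  out <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    val <- v[i, j]
    if (is.na(val) || val < min_height) next
    r <- win_a * val + win_b
    rc <- ceiling(r / cell_size) + 1L
    is_top <- TRUE
    for (ii in max(1, i - rc):min(nr, i + rc)) {
      for (jj in max(1, j - rc):min(nc, j + rc)) {
        if (ii == i && jj == j) next
        w <- v[ii, jj]
        if (is.na(w)) next
        d <- sqrt((ii - i)^2 + (jj - j)^2) * cell_size
        adj <- if (neighborhood == "queen") abs(ii - i) <= 1 && abs(jj - j) <= 1
               else abs(ii - i) + abs(jj - j) <= 1
        if (d <= r + 1e-12 || adj) {
          if (w > val ||
              (w == val && (ii - 1) * nc + jj < (i - 1) * nc + j)) {
            is_top <- FALSE; break
          }
        }
      }
      if (!is_top) break
    }
    if (is_top) out <- rbind(out, c(i, j))
  }
  out
}

# Candidate-side matching criteria, literal restatement: a candidate is TP
# iff its nearest truth point is closer than max_d and no other candidate is
# closer to that truth point (distance ties by candidate id); a truth point
# is FN iff no candidate is within max_d of it.
matchOracle <- function(cands, truth, max_d = 5) {
  nc <- nrow(cands); nt <- nrow(truth)
  tp <- 0; fp <- 0
  if (nc > 0 && nt == 0) fp <- nc
  for (k in seq_len(if (nt == 0) 0 else nc)) {
    d <- sqrt((truth$x - cands$x[k])^2 + (truth$y - cands$y[k])^2)
    g <- which.min(d)
    if (d[g] >= max_d) { fp <- fp + 1; next }
    dg <- sqrt((cands$x - truth$x[g])^2 + (cands$y - truth$y[g])^2)
    better <- dg < dg[k] | (dg == dg[k] & cands$id < cands$id[k])
    if (any(better)) fp <- fp + 1 else tp <- tp + 1
  }
  fn <- 0
  for (k in seq_len(nt)) {
    if (nc == 0 ||
        min(sqrt((cands$x - truth$x[k])^2 + (cands$y - truth$y[k])^2)) >= max_d)
      fn <- fn + 1
  }
  list(TP = tp, FP = fp, FN = fn)
}
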