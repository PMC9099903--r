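cands <- function(x, y, id = sprintf("c%02d", seq_along(x)), height = NA_real_) {
  treeCandidates(id, x, y, height, "GSV")
}

test_that("a close pair merges to its midpoint with a deterministic id", {
  out <- mergeCandidates(cands(c(0, 3), c(0, 0), height = c(5, 8)))
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$x, out$y), c(1.5, 0))
  expect_equal(out$id, "c01+c02")     # sorted member ids
  expect_equal(out$height, 8)         # max member height
  expect_equal(out$source, "merged")
})

test_that("candidates beyond the threshold stay put", {
  out <- mergeCandidates(cands(c(0, 10), c(0, 0)))
  expect_equal(nrow(out), 2L)
  expect_setequal(out$x, c(0, 10))
})

test_that("tangency at exactly the merge distance does not merge", {
  out <- mergeCandidates(cands(c(0, 4), c(0, 0)), mergeParams(merge_distance = 4))
  expect_equal(nrow(out), 2L)
})

test_that("chains merge transitively even past the pairwise threshold", {
  out <- mergeCandidates(cands(c(0, 3, 6), c(0, 0, 0)))
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$x, out$y), c(3, 0))
})

test_that("merging reaches a fixed point and never increases counts", {
  set.seed(77)
  for (rep_i in 1:20) {
    n <- sample(5:40, 1)
    cc <- cands(runif(n, 0, 30), runif(n, 0, 30))
    out <- mergeCandidates(cc)
    expect_lte(nrow(out), n)
    # fixed point: no two output centroids closer than the threshold,
    # so re-merging changes nothing
    if (nrow(out) > 1) {
      d <- as.matrix(dist(out[, c("x", "y")])); diag(d) <- Inf
      expect_gte(min(d), 4)
    }
    again <- mergeCandidates(out)
    expect_equal(again[, c("x", "y")], out[, c("x", "y")])
    # every output position lies in the bounding box of the inputs
    expect_true(all(out$x >= min(cc$x) & out$x <= max(cc$x)))
    expect_true(all(out$y >= min(cc$y) & out$y <= max(cc$y)))
  }
})

test_that("a vanishing threshold is the identity on distinct points", {
  cc <- cands(c(0, 0.5, 1.2), c(0, 0, 0))
  out <- mergeCandidates(cc, mergeParams(merge_distance = 1e-9))
  expect_equal(nrow(out), 3L)
  expect_setequal(out$x, cc$x)
})

test_that("single-pass mode can leave chained centroids unresolved", {
  # two pairs whose pass-1 centroids land 3 m apart
  cc <- cands(c(0, 1, 4, 5), c(0, 0, 0, 0))
  one <- mergeCandidates(cc, mergeParams(iterate = FALSE))
  expect_equal(attr(one, "n_passes"), 1L)
  full <- mergeCandidates(cc, mergeParams(iterate = TRUE))
  expect_equal(nrow(full), 1L)
  expect_gte(nrow(one), nrow(full))
})

test_that("the polygon-centroid rule agrees with point centroids for a pair", {
  cc <- cands(c(0, 3), c(0, 0))
  out <- mergeCandidates(cc, mergeParams(position_rule = "polygon_centroid"))
  expect_equal(nrow(out), 1L)
  # for two equal circles the union centroid is the midpoint
  expect_equal(c(out$x, out$y), c(1.5, 0), tolerance = 0.05)
})

test_that("component membership is logged", {
  out <- mergeCandidates(cands(c(0, 3, 20), c(0, 0, 0)))
  mem <- attr(out, "members")
  expect_setequal(mem$member, c("c01", "c02", "c03"))
  expect_equal(sort(unique(mem$component)), c("c01+c02", "c03"))
})
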