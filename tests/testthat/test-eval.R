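pts <- function(x, y, prefix = "p") {
  data.frame(id = sprintf("%s%02d", prefix, seq_along(x)), x = x, y = y,
             stringsAsFactors = FALSE)
}

test_that("matching applies the three criteria literally", {
  # in range and unique: TP
  m <- matchCandidates(pts(4.9, 0, "c"), pts(0, 0, "g"))
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 0, 0))
  # second candidate loses to a closer one: FP, but the truth is not missed
  m <- matchCandidates(pts(c(1, 2), c(0, 0), "c"), pts(0, 0, "g"))
  expect_equal(c(m$TP, m$FP, m$FN), c(1, 1, 0))
  expect_equal(m$tp_pairs$candidate_id, "c01")
  # out of range: FP and FN
  m <- matchCandidates(pts(6, 0, "c"), pts(0, 0, "g"))
  expect_equal(c(m$TP, m$FP, m$FN), c(0, 1, 1))
  # exactly 5 m is not a match (strict inequality)
  m <- matchCandidates(pts(5, 0, "c"), pts(0, 0, "g"))
  expect_equal(c(m$TP, m$FP, m$FN), c(0, 1, 1))
  # distance ties broken by candidate id
  m <- matchCandidates(pts(c(-1, 1), c(0, 0), "c"), pts(0, 0, "g"))
  expect_equal(m$tp_pairs$candidate_id, "c01")
  # empty sets
  m <- matchCandidates(pts(numeric(), numeric()), pts(numeric(), numeric()))
  expect_equal(c(m$TP, m$FP, m$FN), c(0, 0, 0))
})

test_that("matching agrees with the literal oracle on random instances", {
  set.seed(41)
  for (rep_i in 1:100) {
    nc <- sample(0:30, 1); nt <- sample(0:30, 1)
    cands <- pts(runif(nc, 0, 40), runif(nc, 0, 40), "c")
    truth <- pts(runif(nt, 0, 40), runif(nt, 0, 40), "g")
    m <- matchCandidates(cands, truth)
    o <- matchOracle(cands, truth)
    expect_equal(c(m$TP, m$FP, m$FN), c(o$TP, o$FP, o$FN),
                 info = paste("instance", rep_i))
    expect_equal(m$TP + m$FP, nc)
    expect_lte(m$TP + m$FN, nt)
  }
})

test_that("metrics reproduce published-style counts to two decimals", {
  m <- computeMetrics(635, 911, 51)
  expect_equal(c(m$p, m$r, m$F1), c(41.07, 92.57, 56.90))
  # rounding p and r first would give F1 = 56.89; the unrounded rule gives 56.90
  m <- computeMetrics(91, 104, 104)
  expect_equal(c(m$p, m$r, m$F1), c(46.67, 46.67, 46.67))
  m <- computeMetrics(0, 5, 5)
  expect_equal(c(m$p, m$r, m$F1), c(0, 0, 0))
  expect_error(computeMetrics(-1, 0, 0))
})

test_that("pooled metrics sum counts before computing rates", {
  m <- pooledMetrics(data.frame(TP = c(2273), FP = c(3255), FN = c(399)))
  expect_equal(c(m$p, m$r, m$F1), c(41.12, 85.07, 55.44))
  m <- pooledMetrics(data.frame(TP = 1953, FP = 457, FN = 781))
  expect_equal(m$r, 71.43)
  # single zone pools to itself
  zone <- matchCandidates(pts(c(1, 20), c(0, 0), "c"), pts(0, 0, "g"))
  expect_equal(pooledMetrics(list(zone))[, c("p", "r", "F1")],
               computeMetrics(zone)[, c("p", "r", "F1")])
  expect_error(pooledMetrics(list()), "at least one")
})

test_that("F1 stays between precision and recall", {
  set.seed(55)
  for (rep_i in 1:50) {
    tp <- sample(0:500, 1); fp <- sample(0:500, 1); fn <- sample(0:500, 1)
    m <- computeMetrics(tp, fp, fn)
    if (m$p > 0 && m$r > 0) {
      expect_gte(m$F1, min(m$p, m$r) - 0.01)
      expect_lte(m$F1, max(m$p, m$r) + 0.01)
    }
  }
})
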