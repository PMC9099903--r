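constStack <- function(value = 100, n = 12, bands = c("R17", "NIR17")) {
  orthoStack(stats::setNames(lapply(bands, function(b) matrix(value, n, n)),
                             bands),
             origin = c(0, n * 0.25), cell_size = 0.25)
}

test_that("zonal statistics on a constant band are mean = value, sd = 0", {
  f <- zonalFeatures(data.frame(x = 1.5, y = 1.5), constStack(100))
  expect_equal(f$R17_mean, 100)
  expect_equal(f$R17_sd, 0)
  expect_equal(attr(f, "n_dropped"), 0L)
})

test_that("zonal sd is the population standard deviation", {
  # 1 x 2 grid with 1 m cells; a radius-1 buffer centered between the two
  # pixel centers covers exactly both
  st <- orthoStack(list(B = matrix(c(0, 10), 1, 2)), origin = c(0, 1),
                   cell_size = 1)
  f <- zonalFeatures(data.frame(x = 1, y = 0.5), st, buffer_radius = 1)
  expect_equal(f$B_mean, 5)
  expect_equal(f$B_sd, 5)  # population sd, not 7.07
})

test_that("buffer membership equals the center-in-circle enumeration", {
  set.seed(14)
  n <- 20
  vals <- matrix(runif(n * n, 0, 255), n, n)
  st <- orthoStack(list(B = vals), origin = c(0, n * 0.25), cell_size = 0.25)
  cx <- st@origin[1] + (seq_len(n) - 0.5) * 0.25
  cy <- st@origin[2] - (seq_len(n) - 0.5) * 0.25
  for (rep_i in 1:10) {
    p <- c(runif(1, 1, 4), runif(1, 1, 4))
    sel <- outer(cy, cx, function(y, x) (x - p[1])^2 + (y - p[2])^2 <= 0.5^2)
    f <- zonalFeatures(data.frame(x = p[1], y = p[2]), st)
    expect_equal(f$B_mean, mean(vals[sel]))
    expect_equal(f$B_sd, sqrt(mean((vals[sel] - mean(vals[sel]))^2)))
  }
})

test_that("zonal features are translation-equivariant", {
  set.seed(15)
  vals <- matrix(runif(144), 12, 12)
  a <- orthoStack(list(B = vals), origin = c(0, 3), cell_size = 0.25)
  b <- orthoStack(list(B = vals), origin = c(50, 83), cell_size = 0.25)
  fa <- zonalFeatures(data.frame(x = 1.4, y = 1.6), a)
  fb <- zonalFeatures(data.frame(x = 51.4, y = 81.6), b)
  expect_equal(fa, fb)
})

test_that("off-raster points are dropped and counted", {
  f <- zonalFeatures(data.frame(id = c("a", "b"), x = c(1.5, 99), y = c(1.5, 99)),
                     constStack())
  expect_equal(nrow(f), 1L)
  expect_equal(f$id, "a")
  expect_equal(attr(f, "n_dropped"), 1L)
})

test_that("a perfectly separating feature ranks first", {
  train <- separableTrainingSet(n = 200, sep = 15)
  sel <- selectFeatures(train, keep_fraction = 0.3, seed = 5)
  expect_equal(sel[1], "f_sep")
  expect_true("f_sep" %in% sel)
  # keep_fraction 1 keeps everything
  expect_setequal(selectFeatures(train, keep_fraction = 1, seed = 5),
                  setdiff(names(train), "class"))
})

test_that("duplicated feature columns never empty the selection", {
  train <- separableTrainingSet(n = 100, sep = 8, p_noise = 1)
  train$f_dup <- train$f_sep
  sel <- selectFeatures(train, keep_fraction = 0.34, seed = 2)
  expect_gte(length(sel), 1L)
  expect_true(any(c("f_sep", "f_dup") %in% sel))
})

test_that("well-separated classes cross-validate almost perfectly", {
  train <- separableTrainingSet(n = 200, sep = 15)
  cl <- trainClassifier(train, classifierSpec("RF", seed = 4))
  expect_gte(cl$cv_accuracy, 0.99)
})

test_that("permuted labels cross-validate at chance level", {
  train <- separableTrainingSet(n = 200, sep = 15, seed = 8)
  set.seed(80)
  train$class <- sample(train$class)
  cl <- trainClassifier(train, classifierSpec("RF", seed = 4))
  expect_gte(cl$cv_accuracy, 0.4)
  expect_lte(cl$cv_accuracy, 0.6)
})

test_that("training is deterministic for a fixed seed across algorithms", {
  train <- separableTrainingSet(n = 120, sep = 10, p_noise = 2)
  for (alg in c("RF", "ANN", "SVM_LINEAR", "SVM_RADIAL")) {
    a <- trainClassifier(train, classifierSpec(alg, cv_folds = 5, seed = 6))
    b <- trainClassifier(train, classifierSpec(alg, cv_folds = 5, seed = 6))
    expect_identical(a$cv_accuracy, b$cv_accuracy, info = alg)
    expect_gte(a$cv_accuracy, 0.95)
  }
  expect_error(classifierSpec("LDA"))
})

test_that("spectral filtering keeps TREE candidates and removes NOT-TREE ones", {
  sc <- generateScene(oneTreeConfig(height = 10, crown = 2.5))
  st <- renderOrtho(sc)
  labeled <- sampleTruthPoints(sc, n = 300)
  train <- buildTrainingSet(labeled, st)
  cl <- trainClassifier(train, classifierSpec("RF", cv_folds = 5, seed = 3))
  tr <- sceneTrees(sc)
  cand <- treeCandidates(c("on_tree", "on_ground"),
                         c(tr$x, tr$x + 8), c(tr$y, tr$y), NA_real_, "GSV")
  out <- filterCandidates(cand, cl, st)
  expect_equal(out$id, "on_tree")
  expect_equal(out$source, "filtered")
  empty <- filterCandidates(cand[0, ], cl, st)
  expect_equal(nrow(empty), 0L)
})
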