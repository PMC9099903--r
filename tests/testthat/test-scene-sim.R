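test_that("scene generation is bitwise-deterministic for a fixed seed", {
  cfg <- smallSceneConfig(seed = 42, noiseless = FALSE)
  a <- generateScene(cfg); b <- generateScene(cfg)
  expect_identical(sceneTrees(a), sceneTrees(b))
  expect_identical(sceneStations(a), sceneStations(b))
  expect_identical(sceneClutter(a), sceneClutter(b))
  sa <- simulateScene(cfg); sb <- simulateScene(cfg)
  expect_identical(cloudPoints(sceneCloud(sa)), cloudPoints(sceneCloud(sb)))
  expect_identical(sceneDetections(sa), sceneDetections(sb))
})

test_that("street placement puts a tree at both endpoints when the length divides", {
  cfg <- sceneConfig(area_width = 120, area_height = 40,
                     street_axes = list(cbind(c(10, 110), c(20, 20))),
                     street_tree_spacing = 10, park_tree_density = 0,
                     building_rects = list(), n_clutter = 0, seed = 1)
  tr <- sceneTrees(generateScene(cfg))
  expect_equal(nrow(tr), 11L)  # 100 m / 10 m spacing, both endpoints
  expect_true(all(tr$zone == "street"))
  # alternating 4 m sidewalk offsets
  expect_setequal(unique(tr$y), c(16, 24))
})

test_that("a building covering the whole area excludes every tree", {
  cfg <- sceneConfig(area_width = 50, area_height = 50,
                     street_axes = list(cbind(c(0, 50), c(25, 25))),
                     park_tree_density = 30,
                     building_rects = list(c(-5, -5, 55, 55)),
                     n_clutter = 0, seed = 2)
  expect_equal(nrow(sceneTrees(generateScene(cfg))), 0L)
})

test_that("generated trees respect minimum spacing and stay out of buildings", {
  cfg <- smallSceneConfig(seed = 9, park_tree_density = 60)
  tr <- sceneTrees(generateScene(cfg))
  d <- as.matrix(dist(tr[, c("x", "y")]))
  diag(d) <- Inf
  expect_gte(min(d), cfg$min_tree_spacing)
  b <- cfg$building_rects[[1]]
  expect_false(any(tr$x >= b[1] & tr$x <= b[3] & tr$y >= b[2] & tr$y <= b[4]))
})

test_that("degenerate area is rejected", {
  expect_error(sceneConfig(area_width = 0), "area")
  expect_error(sceneConfig(height_range = c(5, 2)), "min <= max")
})

test_that("realized point density is within 10% of the request", {
  cfg <- sceneConfig(area_width = 50, area_height = 50,
                     street_axes = list(cbind(c(0, 50), c(25, 25))),
                     park_tree_density = 10, building_rects = list(),
                     n_clutter = 0, point_density = 14, seed = 5)
  sc <- generateScene(cfg)
  n <- nrow(cloudPoints(renderPointCloud(sc)))
  expect_gte(n, 14 * 2500 * 0.9)
  expect_lte(n, 14 * 2500 * 1.1)
  expect_error(renderPointCloud(sc, density = 0), "positive")
})

test_that("crown model bounds the maximum return height", {
  sc <- generateScene(oneTreeConfig(height = 10, crown = 2))
  expect_equal(nrow(sceneTrees(sc)), 1L)
  z <- cloudPoints(renderPointCloud(sc))$z
  expect_gt(max(z), 9)      # apex sampled under the paraboloid model
  expect_lte(max(z), 10.5)  # apex + truncated noise (3 sd = 0.3 m)
})

test_that("a scene without raised objects renders an all-ground cloud", {
  cfg <- sceneConfig(area_width = 30, area_height = 30,
                     street_axes = list(cbind(c(0, 30), c(15, 15))),
                     street_tree_spacing = 100, street_tree_offset = 25,
                     park_tree_density = 0, building_rects = list(),
                     n_clutter = 0, seed = 4)
  sc <- generateScene(cfg)
  expect_equal(nrow(sceneTrees(sc)), 0L)
  expect_true(all(cloudPoints(renderPointCloud(sc))$z == 0))
})

test_that("ortho raster shape and class spectra follow the scene", {
  sc <- generateScene(oneTreeConfig(height = 10, crown = 2))
  st <- renderOrtho(sc)
  expect_equal(gridDim(st), c(ceiling(20 / 0.25), ceiling(20 / 0.25)))
  expect_setequal(bandNames(st), names(defaultSpectralParams()$TREE$mean))
  tr <- sceneTrees(sc)
  sp <- sc@config$spectral_params
  for (b in bandNames(st)) {
    g <- getBand(st, b)
    ij <- cellIndex(g, tr$x, tr$y)
    # pixel at the tree center comes from the TREE distribution
    expect_lt(abs(gridValues(g)[ij] - sp$TREE$mean[[b]]), 4 * sp$TREE$sd[[b]])
  }
  # a treeless scene draws every pixel from the NOT-TREE distribution
  bare <- generateScene(sceneConfig(
    area_width = 20, area_height = 20,
    street_axes = list(cbind(c(0, 20), c(10, 10))),
    street_tree_spacing = 100, street_tree_offset = 30,
    park_tree_density = 0, building_rects = list(), n_clutter = 0, seed = 6))
  st0 <- renderOrtho(bare)
  for (b in bandNames(st0)) {
    g <- gridValues(getBand(st0, b))
    expect_lt(abs(mean(g) - sp$NOT_TREE$mean[[b]]), 1)
    expect_lt(abs(sd(as.vector(g)) - sp$NOT_TREE$sd[[b]]), 1)
  }
})

test_that("zero-noise detections invert exactly through the geolocation model", {
  sc <- generateScene(smallSceneConfig(seed = 7))
  det <- simulateDetections(sc)
  expect_gt(nrow(det), 0)
  loc <- locateTrees(sceneStations(sc), det, model = "equirect")
  tr <- sceneTrees(sc)
  err <- vapply(seq_len(nrow(loc)), function(k) {
    t <- tr[tr$id == loc$truth_id[k], ]
    sqrt((t$x - loc$x[k])^2 + (t$y - loc$y[k])^2)
  }, numeric(1))
  expect_lt(max(err), 1e-6)
})

test_that("miss_rate 1 leaves only spurious detections", {
  sc <- generateScene(smallSceneConfig(seed = 7, detection_miss_rate = 1,
                                       false_detection_rate = 1))
  det <- simulateDetections(sc)
  expect_true(all(is.na(det$truth_id)))
  expect_gt(nrow(det), 0)
})

test_that("spurious detection targets stay clear of true trees", {
  sc <- generateScene(smallSceneConfig(seed = 8, false_detection_rate = 2))
  det <- simulateDetections(sc)
  loc <- locateTrees(sceneStations(sc), det, model = "equirect")
  tr <- sceneTrees(sc)
  sp <- loc[is.na(loc$truth_id), ]
  for (k in seq_len(nrow(sp)))
    expect_gt(min(sqrt((tr$x - sp$x[k])^2 + (tr$y - sp$y[k])^2)), 5)
})
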