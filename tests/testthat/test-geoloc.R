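station <- function(...) {
  utils::modifyList(
    list(id = "S1", x = 0, y = 0, heading = 0, pitch = 0, hfov = 90,
         vfov = 90, img_width = 1000, img_height = 1000, camera_height = 2.5),
    list(...))
}

test_that("pixel columns map to bearings under both camera models", {
  st <- station()
  expect_equal(pixelToBearing(st, 500, "perspective"), 0)  # optical axis
  expect_equal(pixelToBearing(st, 500, "equirect"), 0)
  expect_equal(pixelToBearing(st, 750, "perspective"),
               atan(0.5 * tan(pi / 4)) * 180 / pi, tolerance = 1e-9)  # 26.565
  expect_equal(pixelToBearing(st, 750, "equirect"), 22.5)
  # heading offsets and wrap-around
  st2 <- station(heading = 350)
  expect_equal(pixelToBearing(st2, 750, "equirect"), 12.5)
  expect_error(pixelToBearing(station(hfov = 200), 10, "perspective"), "hfov")
  expect_error(pixelToBearing(st, 1000), "outside")
})

test_that("stem-base rows map to ground distances by the depression model", {
  st <- station()
  v10 <- 500 * (1 + tan(10 * pi / 180))  # row of a 10 degree depression
  expect_equal(pixelToDistance(st, v10), 2.5 / tan(10 * pi / 180),
               tolerance = 1e-9)  # 14.178 m
  st120 <- station(vfov = 120)
  v45 <- 500 * (1 + tan(pi / 4) / tan(pi / 3))
  expect_equal(pixelToDistance(st120, v45), 2.5, tolerance = 1e-9)
  # the horizon row carries no distance
  expect_error(pixelToDistance(st, 500), "horizon")
  expect_error(pixelToDistance(st, 499), "horizon")
})

test_that("observations project by bearing/distance trigonometry", {
  st <- station(x = 100, y = 200)
  expect_equal(projectObservation(st, 90, 10), c(110, 200))
  expect_equal(projectObservation(st, 0, 10), c(100, 210))
  expect_equal(projectObservation(st, 225, sqrt(2)), c(99, 199))
  expect_error(projectObservation(st, 0, 0), "positive")
})

test_that("bearing and distance models round-trip through their inverses", {
  for (model in c("perspective", "equirect")) {
    st <- station(heading = 37, hfov = if (model == "equirect") 360 else 90)
    for (b in c(37, 5.2, 71.9, if (model == "equirect") c(180, 271.3))) {
      u <- urbantrees:::bearingToPixel(st, b, model)
      expect_lt(abs(pixelToBearing(st, u, model) - b), 1e-9)
    }
  }
  st <- station()
  for (d in c(3, 10, 50.7)) {
    v <- urbantrees:::distanceToPixel(st, d)
    expect_lt(abs(pixelToDistance(st, v) - d), 1e-9)
  }
})

test_that("locateTrees drops horizon detections and keeps the rest", {
  st <- data.frame(station(), stringsAsFactors = FALSE)
  det <- data.frame(station_id = "S1", kind = "stem",
                    u = c(500, 500), v = c(750, 400))  # second above horizon
  out <- locateTrees(st, det, "perspective")
  expect_equal(nrow(out), 1L)
  expect_equal(attr(out, "n_dropped"), 1L)
  expect_equal(out$source, "GSV")
  expect_equal(nrow(locateTrees(st, det[0, ], "perspective")), 0L)
  bad <- det; bad$station_id <- "NOPE"
  expect_error(locateTrees(st, bad, "perspective"), "unknown station")
})

test_that("the three-image consistency check keeps, repositions, and rejects", {
  stations <- data.frame(id = c("S1", "S2", "S3", "S4"),
                         x = c(0, 10, 20, 90), y = 0, heading = 0, pitch = 0,
                         hfov = 360, vfov = 90, img_width = 100,
                         img_height = 100, camera_height = 2.5,
                         stringsAsFactors = FALSE)
  cand <- treeCandidates("c1", 5, 5, NA_real_, "GSV")

  fake <- function(positions) {
    function(stn, cd) positions[[stn$id]]
  }
  # all three consistent: kept at the centroid
  det <- fake(list(S1 = c(0, 0), S2 = c(2, 0), S3 = c(1, 2)))
  out <- verifyCandidates(cand, stations, det, verifyParams())
  expect_equal(nrow(out), 1L)
  expect_equal(c(out$x, out$y), c(1, 2 / 3), tolerance = 1e-12)
  expect_equal(out$source, "filtered")
  expect_equal(out$id, "c1")

  # one outlier position: rejected (pairwise distance 12.8 > 4)
  det <- fake(list(S1 = c(0, 0), S2 = c(2, 0), S3 = c(10, 10)))
  expect_equal(nrow(verifyCandidates(cand, stations, det, verifyParams())), 0L)

  # missing re-detection in one of the three images: rejected
  det <- fake(list(S1 = c(0, 0), S2 = c(2, 0), S3 = NULL))
  expect_equal(nrow(verifyCandidates(cand, stations, det, verifyParams())), 0L)

  expect_error(verifyCandidates(cand, stations[1:2, ], det, verifyParams()),
               "fewer than k_images")
})

test_that("verification moves positions by less than the consistency distance", {
  sc <- generateScene(smallSceneConfig(seed = 13, false_detection_rate = 1))
  det <- simulateDetections(sc)
  loc <- locateTrees(sceneStations(sc), det, "equirect")
  merged <- mergeCandidates(loc)
  provider <- makeDetectionProvider(sceneStations(sc), det, "equirect")
  out <- verifyCandidates(merged, sceneStations(sc), provider)
  expect_true(all(out$id %in% merged$id))
  for (k in seq_len(nrow(out))) {
    orig <- merged[merged$id == out$id[k], ]
    expect_lte(sqrt((orig$x - out$x[k])^2 + (orig$y - out$y[k])^2), 4)
  }
})
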