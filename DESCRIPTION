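Package: urbantrees
Title: Two-Stage Urban Tree Inventory from Airborne LiDAR and Street-Level Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic urban tree inventory in two stages: stage one
    detects every candidate tree, either by variable-window local-maxima
    treetop detection on a smoothed, building-clipped canopy height model
    rasterized from airborne laser scanning point clouds, or by geolocating
    per-image tree detections from street-level panoramas (bearing and
    stem-base depression-angle trigonometry); stage two debugs false
    positives, either by checking detection consistency across the three
    nearest panorama stations or by a TREE / NOT-TREE spectral classifier on
    zonal orthophoto statistics. Nearby candidates are merged by buffer-union
    after every stage. Includes the distance-based true-positive matching
    rules with precision, recall and F1 evaluation, and a seeded synthetic
    city-scene simulator (trees, buildings, point cloud, orthophoto bands,
    panorama detections) so the whole pipeline is testable end to end with
    known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    randomForest,
    nnet,
    e1071
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'urbantrees-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'geometry.R'
    'raster.R'
    'pointcloud.R'
    'ortho.R'
    'candidates.R'
    'scene.R'
    'chm.R'
    'itd.R'
    'geoloc.R'
    'merge.R'
    'spectral.R'
    'eval.R'
    'pipeline.R'
    'io.R'
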