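#' Run one method combination of the two-stage inventory pipeline
#'
#' Orchestrates the six method combinations over a synthetic scene (or
#' equivalent pre-loaded inputs). Stage 1 over-detects: `ALS` rasterizes the
#' point cloud to a 0.25 m CHM, smooths it (3x3 mean), clips buildings and
#' runs variable-window treetop detection; `GSV` geolocates every per-image
#' stem detection. Candidates closer than the merge distance are fused after
#' every stage. Stage 2 (optional) debugs false positives: `+GSV` keeps only
#' candidates re-detected consistently in their three nearest panorama
#' images; `+ML` keeps only candidates classified TREE from zonal orthophoto
#' spectra. The final merged candidates are scored against the ground-truth
#' trees.
#'
#' @param scene an [UrbanScene-class] (from [simulateScene()]); detections,
#'   cloud and ortho are rendered on demand if missing
#' @param method one of `"GSV", "ALS", "GSV+GSV", "GSV+ML", "ALS+GSV",
#'   "ALS+ML"`
#' @param itd_params [itdParams()] for the ALS path
#' @param clip_buffer clearance passed to [clipBuildings()] (m). The default,
#'   two cell sizes, removes every cell whose smoothed value can contain roof
#'   returns (the wall-straddling cell plus the 3x3 kernel reach), which
#'   would otherwise leave a halo of spurious local maxima along walls.
#' @param verify_params [verifyParams()] for the `+GSV` stage
#' @param classifier_spec [classifierSpec()] for the `+ML` stage
#' @param merge_params [mergeParams()] applied after every stage
#' @param eval_params [evalParams()] for scoring
#' @param out_dir optional directory; when given, candidates (GeoJSON + CSV),
#'   metrics (CSV) and a stage-count log are written there
#' @param seed seed for the ML stage (feature selection, CV folds, model)
#' @return list with `stage1`, `stage1_merged`, `stage2`, `final` candidate
#'   tables, the `match` result, `metrics`, the fitted `classifier` (ML
#'   methods), and a `log` data.frame of per-stage candidate counts
#' @export
runPipeline <- function(scene, method = c("GSV", "ALS", "GSV+GSV", "GSV+ML",
                                          "ALS+GSV", "ALS+ML"),
                        itd_params = itdParams(),
                        clip_buffer = 0.5,
                        verify_params = verifyParams(),
                        classifier_spec = classifierSpec(),
                        merge_params = mergeParams(),
                        eval_params = evalParams(),
                        out_dir = NULL, seed = 1L) {
  method <- match.arg(method)
  parts <- strsplit(method, "+", fixed = TRUE)[[1]]
  stage1 <- parts[1]; stage2 <- if (length(parts) > 1) parts[2] else NA
  cfg <- scene@config
  log <- data.frame(stage = character(), n = integer())
  note <- function(stage, n) log <<- rbind(log, data.frame(stage = stage, n = n))

  detections <- scene@detections
  if (!nrow(detections) && (stage1 == "GSV" || identical(stage2, "GSV")))
    detections <- simulateDetections(scene)

  if (stage1 == "ALS") {
    cloud <- scene@cloud
    if (!nrow(cloud@points)) cloud <- renderPointCloud(scene)
    chm <- rasterizeCHM(cloud, cell_size = 0.25,
                        extent = c(0, 0, cfg$area_width, cfg$area_height))
    chm <- smoothCHM(chm, window = 3)
    chm <- clipBuildings(chm, scene@buildings, buffer = clip_buffer)
    cand1 <- detectTreetops(chm, itd_params)
  } else {
    if (!nrow(scene@stations)) stop("GSV method requires stations")
    cand1 <- locateTrees(scene@stations, detections, model = cfg$pixel_model)
  }
  note(paste0("stage1_", stage1), nrow(cand1))
  merged1 <- mergeCandidates(cand1, merge_params)
  note("stage1_merged", nrow(merged1))

  classifier <- NULL
  if (is.na(stage2)) {
    cand2 <- merged1
  } else if (stage2 == "GSV") {
    provider <- makeDetectionProvider(
      scene@stations, detections, model = cfg$pixel_model,
      max_offset = verify_params$consistency_distance)
    cand2 <- verifyCandidates(merged1, scene@stations, provider, verify_params)
    note("stage2_GSV", nrow(cand2))
  } else {
    ortho <- scene@ortho
    if (identical(bandNames(ortho), "empty")) ortho <- renderOrtho(scene)
    labeled <- sampleTruthPoints(scene)
    train <- buildTrainingSet(labeled, ortho)
    sel <- selectFeatures(train, keep_fraction = 0.5, seed = seed)
    spec <- classifier_spec; spec$seed <- as.integer(seed)
    classifier <- trainClassifier(train, spec, features = sel)
    cand2 <- filterCandidates(merged1, classifier, ortho)
    note("stage2_ML", nrow(cand2))
  }
  final <- if (is.na(stage2)) merged1 else mergeCandidates(cand2, merge_params)
  note("final", nrow(final))

  match <- matchCandidates(final, scene@trees, eval_params)
  metrics <- computeMetrics(match)
  metrics$method <- method

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    stub <- gsub("\\+", "_", method)
    writeCandidatesGeoJSON(final, file.path(out_dir, paste0(stub, "_trees.geojson")))
    writeCandidatesCSV(final, file.path(out_dir, paste0(stub, "_trees.csv")))
    write.csv(metrics, file.path(out_dir, paste0(stub, "_metrics.csv")),
              row.names = FALSE)
    write.csv(log, file.path(out_dir, paste0(stub, "_log.csv")),
              row.names = FALSE)
  }
  list(method = method, stage1 = cand1, stage1_merged = merged1,
       stage2 = cand2, final = final, match = match, metrics = metrics,
       classifier = classifier, log = log)
}
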