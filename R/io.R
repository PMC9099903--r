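# Plain-text geospatial I/O: GeoJSON for points and polygons, CSV schemas for
# stations / detections / candidates, YAML for scene configs.

#' Write/read point tables as GeoJSON
#'
#' Any columns besides `x`/`y` become feature properties.
#'
#' @param df data.frame with `x`, `y` and property columns
#' @param path file path
#' @return `readPointsGeoJSON` returns the data.frame back.
#' @export
writePointsGeoJSON <- function(df, path) {
  props <- setdiff(names(df), c("x", "y"))
  features <- lapply(seq_len(nrow(df)), function(k) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$x[k], df$y[k])),
         properties = as.list(df[k, props, drop = FALSE]))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features), path,
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' @rdname writePointsGeoJSON
#' @export
readPointsGeoJSON <- function(path) {
  g <- jsonlite::read_json(path)
  rows <- lapply(g$features, function(f) {
    p <- f$properties
    p[vapply(p, is.null, logical(1))] <- NA
    cbind(data.frame(x = f$geometry$coordinates[[1]],
                     y = f$geometry$coordinates[[2]]),
          as.data.frame(p, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write/read polygon lists as GeoJSON
#'
#' @param polys list of two-column coordinate matrices (unclosed rings)
#' @param path file path
#' @return `readPolygonsGeoJSON` returns a list of matrices.
#' @export
writePolygonsGeoJSON <- function(polys, path) {
  features <- lapply(polys, function(m) {
    ring <- rbind(m, m[1, , drop = FALSE])  # close the ring
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))),
         properties = stats::setNames(list(), character()))
  })
  jsonlite::write_json(
    list(type = "FeatureCollection", features = features), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePolygonsGeoJSON
#' @export
readPolygonsGeoJSON <- function(path) {
  g <- jsonlite::read_json(path)
  lapply(g$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    m[-nrow(m), , drop = FALSE]  # unclose
  })
}

#' Candidate, station and detection tables as CSV
#'
#' Documented column schemas: candidates `id,x,y,height,source`; stations
#' `id,x,y,heading,pitch,hfov,vfov,img_width,img_height,camera_height,
#' capture_date`; detections `station_id,kind,u,v,confidence[,truth_id]`.
#'
#' @param df the table
#' @param path file path
#' @return readers return validated data.frames.
#' @export
writeCandidatesCSV <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCandidatesCSV
#' @export
readCandidatesCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$id <- as.character(df$id)
  validateCandidates(df)
  df
}

#' @rdname writeCandidatesCSV
#' @export
writeStationsCSV <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCandidatesCSV
#' @export
readStationsCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "x", "y", "heading", "pitch", "hfov", "vfov",
            "img_width", "img_height", "camera_height")
  if (!all(need %in% names(df)))
    stop("stations CSV needs columns: ", paste(need, collapse = ", "))
  df$id <- as.character(df$id)
  df
}

#' @rdname writeCandidatesCSV
#' @export
writeDetectionsCSV <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCandidatesCSV
#' @export
readDetectionsCSV <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "kind", "u", "v")
  if (!all(need %in% names(df)))
    stop("detections CSV needs columns: ", paste(need, collapse = ", "))
  df$station_id <- as.character(df$station_id)
  df
}

#' Write/read a GeoJSON candidate layer
#'
#' @param candidates candidate data.frame
#' @param path file path
#' @return `readCandidatesGeoJSON` returns a candidate data.frame.
#' @export
writeCandidatesGeoJSON <- function(candidates, path) {
  writePointsGeoJSON(candidates, path)
}

#' @rdname writeCandidatesGeoJSON
#' @export
readCandidatesGeoJSON <- function(path) {
  df <- readPointsGeoJSON(path)
  df$id <- as.character(df$id)
  validateCandidates(df)
  df
}

#' Write/read a scene configuration as YAML
#'
#' Matrix-valued entries (street axes) are stored as coordinate lists.
#'
#' @param config a [sceneConfig()]
#' @param path file path
#' @return `readSceneConfigYAML` returns a [sceneConfig()].
#' @export
writeSceneConfigYAML <- function(config, path) {
  cfg <- unclass(config)
  cfg$street_axes <- lapply(cfg$street_axes, function(m)
    lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ])))
  cfg$spectral_params <- lapply(cfg$spectral_params, function(cl)
    list(mean = as.list(cl$mean), sd = as.list(cl$sd)))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname writeSceneConfigYAML
#' @export
readSceneConfigYAML <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$street_axes <- lapply(cfg$street_axes, function(vv)
    do.call(rbind, lapply(vv, unlist)))
  cfg$spectral_params <- lapply(cfg$spectral_params, function(cl)
    list(mean = unlist(cl$mean), sd = unlist(cl$sd)))
  do.call(sceneConfig, cfg)
}
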