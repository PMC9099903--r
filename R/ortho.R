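#' Create an OrthoStack
#'
#' @param bands named list of numeric matrices with identical dimensions.
#' @param origin numeric(2), shared top-left corner.
#' @param cell_size shared cell size in meters.
#' @return an [OrthoStack-class]
#' @export
orthoStack <- function(bands, origin, cell_size = 0.25) {
  bands <- lapply(bands, function(b) { storage.mode(b) <- "double"; b })
  new("OrthoStack", origin = as.numeric(origin),
      cellSize = as.numeric(cell_size), bands = bands)
}

#' @rdname OrthoStack-class
#' @export
setMethod("bandNames", "OrthoStack", function(x) names(x@bands))

#' @rdname OrthoStack-class
#' @export
setMethod("getBand", "OrthoStack", function(x, name) {
  if (!name %in% names(x@bands)) stop("unknown band: ", name)
  rasterGrid(x@bands[[name]], origin = x@origin, cell_size = x@cellSize)
})

#' @rdname OrthoStack-class
#' @export
setMethod("gridOrigin", "OrthoStack", function(x) x@origin)

#' @rdname OrthoStack-class
#' @export
setMethod("cellSize", "OrthoStack", function(x) x@cellSize)

#' @rdname OrthoStack-class
#' @export
setMethod("gridDim", "OrthoStack", function(x) dim(x@bands[[1]]))

setMethod("show", "OrthoStack", function(object) {
  d <- dim(object@bands[[1]])
  cat("OrthoStack:", length(object@bands), "bands (",
      paste(names(object@bands), collapse = ", "), ")\n")
  cat("  grid:", d[1], "x", d[2], "cells @", object@cellSize, "m\n")
})

#' Read/write an OrthoStack as per-band ASCII grids plus a YAML band map
#'
#' Each band goes to `<prefix>_<band>.asc`; `<prefix>_bands.yml` records the
#' band order so the stack can be reassembled.
#'
#' @param stack an [OrthoStack-class]
#' @param prefix path prefix for the band files
#' @return `readOrthoStack` returns an [OrthoStack-class].
#' @export
writeOrthoStack <- function(stack, prefix) {
  files <- character()
  for (b in names(stack@bands)) {
    f <- paste0(prefix, "_", b, ".asc")
    writeAsciiGrid(getBand(stack, b), f)
    files[b] <- basename(f)
  }
  yaml::write_yaml(list(bands = as.list(files)), paste0(prefix, "_bands.yml"))
  invisible(prefix)
}

#' @rdname writeOrthoStack
#' @export
readOrthoStack <- function(prefix) {
  map <- yaml::read_yaml(paste0(prefix, "_bands.yml"))$bands
  dirn <- dirname(prefix)
  bands <- list()
  g <- NULL
  for (b in names(map)) {
    g <- readAsciiGrid(file.path(dirn, map[[b]]))
    bands[[b]] <- gridValues(g)
  }
  orthoStack(bands, origin = gridOrigin(g), cell_size = cellSize(g))
}
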