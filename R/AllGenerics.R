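#' @rdname RasterGrid-class
#' @param x a RasterGrid or OrthoStack
#' @export
setGeneric("gridOrigin", function(x) standardGeneric("gridOrigin"))

#' @rdname RasterGrid-class
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))

#' @rdname RasterGrid-class
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname RasterGrid-class
#' @export
setGeneric("gridDim", function(x) standardGeneric("gridDim"))

#' @rdname OrthoStack-class
#' @param x an OrthoStack
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))

#' @rdname OrthoStack-class
#' @param name band name
#' @export
setGeneric("getBand", function(x, name) standardGeneric("getBand"))

#' @rdname PointCloud-class
#' @param x a PointCloud
#' @export
setGeneric("cloudPoints", function(x) standardGeneric("cloudPoints"))

#' @rdname UrbanScene-class
#' @param x an UrbanScene
#' @export
setGeneric("sceneTrees", function(x) standardGeneric("sceneTrees"))

#' @rdname UrbanScene-class
#' @export
setGeneric("sceneStations", function(x) standardGeneric("sceneStations"))

#' @rdname UrbanScene-class
#' @export
setGeneric("sceneBuildings", function(x) standardGeneric("sceneBuildings"))

#' @rdname UrbanScene-class
#' @export
setGeneric("sceneDetections", function(x) standardGeneric("sceneDetections"))

#' @rdname UrbanScene-class
#' @export
setGeneric("sceneCloud", function(x) standardGeneric("sceneCloud"))

#' @rdname UrbanScene-class
#' @export
setGeneric("sceneOrtho", function(x) standardGeneric("sceneOrtho"))

#' @rdname UrbanScene-class
#' @export
setGeneric("sceneClutter", function(x) standardGeneric("sceneClutter"))
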