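#' Accessors for OrganoidStack classes
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x an OrganoidStack object.
#' @return the slot value.
#' @name accessors
#' @aliases sceneObjects gelDepth xyExtent sceneDensity nLayers stepSize
#'   layerPositions pixelSize channelNames indexMap objectRecords nObjects
#'   totalArea overlapRateOf backgroundMean chemoCallOf
NULL

#' @rdname accessors
#' @export
setGeneric("sceneObjects", function(x) standardGeneric("sceneObjects"))
#' @rdname accessors
#' @export
setGeneric("gelDepth", function(x) standardGeneric("gelDepth"))
#' @rdname accessors
#' @export
setGeneric("xyExtent", function(x) standardGeneric("xyExtent"))
#' @rdname accessors
#' @export
setGeneric("sceneDensity", function(x) standardGeneric("sceneDensity"))
#' @rdname accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))
#' @rdname accessors
#' @export
setGeneric("stepSize", function(x) standardGeneric("stepSize"))
#' @rdname accessors
#' @export
setGeneric("layerPositions", function(x) standardGeneric("layerPositions"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setGeneric("indexMap", function(x) standardGeneric("indexMap"))
#' @rdname accessors
#' @export
setGeneric("objectRecords", function(x) standardGeneric("objectRecords"))
#' @rdname accessors
#' @export
setGeneric("nObjects", function(x) standardGeneric("nObjects"))
#' @rdname accessors
#' @export
setGeneric("totalArea", function(x) standardGeneric("totalArea"))
#' @rdname accessors
#' @export
setGeneric("backgroundMean", function(x) standardGeneric("backgroundMean"))

#' @rdname labelingRate
#' @export
setGeneric("labelingRate", function(x, greenThreshold = defaultGreenThreshold(), ...)
  standardGeneric("labelingRate"))

#' @rdname overlapRate
#' @export
setGeneric("overlapRate", function(x, mode = c("ground_truth", "detected"), ...)
  standardGeneric("overlapRate"))

#' @rdname survivalRate
#' @export
setGeneric("survivalRate", function(pair, ...) standardGeneric("survivalRate"))

#' @rdname sizeChangeRatio
#' @export
setGeneric("sizeChangeRatio", function(pair, ...) standardGeneric("sizeChangeRatio"))

#' @rdname applyStaining
#' @export
setGeneric("applyStaining", function(scene, staining, seed = NULL)
  standardGeneric("applyStaining"))

#' @rdname applyTreatment
#' @export
setGeneric("applyTreatment", function(scene, effect, seed = NULL)
  standardGeneric("applyTreatment"))
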