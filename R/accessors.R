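#' @rdname accessors
setMethod("sceneObjects", "Scene", function(x) x@objects)
#' @rdname accessors
setMethod("gelDepth", "Scene", function(x) x@gelDepth)
#' @rdname accessors
setMethod("xyExtent", "Scene", function(x) x@xyExtent)
#' @rdname accessors
setMethod("sceneDensity", "Scene", function(x) x@density)

#' @rdname accessors
setMethod("nLayers", "AcquisitionPlan", function(x) x@nLayers)
#' @rdname accessors
setMethod("stepSize", "AcquisitionPlan", function(x) x@step)
#' @rdname accessors
setMethod("layerPositions", "AcquisitionPlan", function(x) x@layerPositions)
#' @rdname accessors
setMethod("layerPositions", "ImageStack", function(x) x@layerPositions)
#' @rdname accessors
setMethod("nLayers", "ImageStack", function(x) dim(x@pixels)[4])

#' @rdname accessors
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "CompositeImage", function(x) x@pixelSize)
#' @rdname accessors
setMethod("channelNames", "ImageStack", function(x) x@channelNames)
#' @rdname accessors
setMethod("channelNames", "CompositeImage", function(x) x@channelNames)
#' @rdname accessors
setMethod("indexMap", "CompositeImage", function(x) x@indexMap)

#' @rdname accessors
setMethod("objectRecords", "WellSummary", function(x) x@records)
#' @rdname accessors
setMethod("nObjects", "WellSummary", function(x) x@nObjects)
#' @rdname accessors
setMethod("totalArea", "WellSummary", function(x) x@totalArea)
#' @rdname accessors
setMethod("backgroundMean", "WellSummary", function(x) x@backgroundMean)

#' Extract one channel of a stack or composite
#'
#' @param x an [ImageStack-class] or [CompositeImage-class].
#' @param channel channel name.
#' @param layer for stacks, 1-based layer index.
#' @return numeric matrix (row, col).
#' @export
getChannel <- function(x, channel, layer = NULL) {
  ci <- match(channel, channelNames(x))
  if (is.na(ci)) stop("channel '", channel, "' not present; available: ",
                      paste(channelNames(x), collapse = ", "), call. = FALSE)
  if (is(x, "ImageStack")) {
    if (is.null(layer)) stop("layer index required for an ImageStack", call. = FALSE)
    x@pixels[, , ci, layer]
  } else {
    x@pixels[, , ci]
  }
}

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene: %d object(s) in %g x %g x %g um gel (%.3g objects/uL), seed %s\n",
              nrow(object@objects), object@xyExtent[1], object@xyExtent[2],
              object@gelDepth, object@density,
              ifelse(is.na(object@seed), "none", object@seed)))
  if (nrow(object@objects)) {
    cat(sprintf("  diameters %g-%g um; %d labeled; mean live fraction %.2f\n",
                min(object@objects$diameter), max(object@objects$diameter),
                sum(object@objects$labeled), mean(object@objects$live_fraction)))
  }
})

setMethod("show", "AcquisitionPlan", function(object) {
  cat(sprintf("AcquisitionPlan: %d layer(s) over %g um, step %g um\n",
              object@nLayers, object@zRange, object@step))
  cat("  planes (um):", paste(object@layerPositions, collapse = ", "), "\n")
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageStack: %d x %d px, %d channel(s) [%s], %d layer(s), %g um/px\n",
              d[1], d[2], d[3], paste(object@channelNames, collapse = ", "),
              d[4], object@pixelSize))
})

setMethod("show", "CompositeImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("CompositeImage: %d x %d px, %d channel(s) [%s], %g um/px\n",
              d[1], d[2], d[3], paste(object@channelNames, collapse = ", "),
              object@pixelSize))
  cat(sprintf("  fused from %s layer(s), reference '%s'\n",
              object@provenance$n_layers %||% "?",
              object@provenance$reference_channel %||% "?"))
})

setMethod("show", "WellSummary", function(object) {
  cat(sprintf("WellSummary: %d object(s), total area %.0f um2\n",
              object@nObjects, object@totalArea))
  cat(sprintf("  labeling %s%%, overlap %s%%, background %s\n",
              format(object@labelingRate), format(object@overlapRate),
              format(object@backgroundMean)))
})

setMethod("show", "TimepointPair", function(object) {
  cat(sprintf("TimepointPair (day %d): d0 n=%d area=%.0f | dN n=%d area=%.0f\n",
              object@day, object@d0@nObjects, object@d0@totalArea,
              object@dN@nObjects, object@dN@totalArea))
})

setMethod("show", "ChemoCall", function(object) {
  cat(sprintf("ChemoCall: size change %.2f%% vs cutoff %.2f%% -> %s\n",
              object@sizeChangeRatio, object@cutoff, object@call))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
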