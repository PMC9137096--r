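#' @import methods
NULL

## column layout of the ground-truth object table carried by a Scene
.sceneCols <- c("id", "x", "y", "z", "diameter", "live_fraction",
                "labeled", "green_intensity", "red_intensity", "shell_width")

#' Optical model of the simulated microscope
#'
#' Describes the imaging side of the simulator: spatial sampling, how fast an
#' object blurs once it leaves the depth-of-field band, how far from a focal
#' plane an object can sit and still be picked up, detector noise, and the
#' baseline background level.
#'
#' @slot pixelSize physical sampling, micrometres per pixel.
#' @slot blurCoeff Gaussian blur growth, micrometres of sigma per micrometre
#'   of defocus beyond the depth-of-field half-depth.
#' @slot dofHalfDepth detectability half-depth h in micrometres: an object of
#'   radius r is visible in a plane when its centre is within r + h of it, and
#'   renders sharp while within h.
#' @slot noiseSd additive Gaussian detector noise (intensity units, images are
#'   scaled to [0, 1]).
#' @slot backgroundBase baseline background intensity B0.
#' @seealso [opticalModel()]
#' @export
setClass("OpticalModel", representation(
  pixelSize = "numeric", blurCoeff = "numeric", dofHalfDepth = "numeric",
  noiseSd = "numeric", backgroundBase = "numeric"
))

setValidity("OpticalModel", function(object) {
  v <- c(pixelSize = object@pixelSize, blurCoeff = object@blurCoeff,
         dofHalfDepth = object@dofHalfDepth, noiseSd = object@noiseSd,
         backgroundBase = object@backgroundBase)
  if (any(!is.finite(v)) || any(v < 0))
    return("all optical parameters must be finite and >= 0")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (object@dofHalfDepth <= 0) return("dofHalfDepth must be > 0")
  TRUE
})

#' Calcein-AM staining / gel-background model
#'
#' Saturating dose-by-time labeling kinetics and linear gel-background growth
#' with copper quenching. The labeling probability is
#' p = min(1, c * t / K); the green gel background after t minutes is
#' B(t) = B0 + beta * t * max(0, 1 - cu / quenchReference).
#'
#' @slot concentration dye concentration c in micromolar.
#' @slot time staining time t in minutes.
#' @slot saturationK saturation constant K in micromolar-minutes; c*t >= K
#'   labels every live object.
#' @slot cuConcentration Cu2+ concentration in millimolar.
#' @slot backgroundRate beta, background intensity gained per minute of
#'   staining without quencher.
#' @slot quenchReference Cu2+ concentration (mM) at which the nonspecific gel
#'   background is fully quenched.
#' @seealso [stainingModel()], [applyStaining()]
#' @export
setClass("StainingModel", representation(
  concentration = "numeric", time = "numeric", saturationK = "numeric",
  cuConcentration = "numeric", backgroundRate = "numeric",
  quenchReference = "numeric"
))

setValidity("StainingModel", function(object) {
  v <- c(object@concentration, object@time, object@saturationK,
         object@cuConcentration, object@backgroundRate, object@quenchReference)
  if (any(!is.finite(v)) || any(v < 0))
    return("all staining parameters must be finite and >= 0")
  TRUE
})

#' Drug / radiation treatment effect
#'
#' Population-level effect applied to a scene: a fraction of objects is fully
#' killed; survivors keep a shrunken live core surrounded by an annulus of
#' loose dead cells.
#'
#' @slot killFraction fraction in [0, 1] of objects fully killed.
#' @slot shrinkFactor multiplier in [0, 1] on the live-core diameter of
#'   surviving objects.
#' @slot deadShellWidth width (micrometres) of the dead-cell shell around
#'   survivors.
#' @seealso [treatmentEffect()], [applyTreatment()]
#' @export
setClass("TreatmentEffect", representation(
  killFraction = "numeric", shrinkFactor = "numeric", deadShellWidth = "numeric"
))

setValidity("TreatmentEffect", function(object) {
  if (object@killFraction < 0 || object@killFraction > 1)
    return("killFraction must be in [0, 1]")
  if (object@shrinkFactor < 0 || object@shrinkFactor > 1)
    return("shrinkFactor must be in [0, 1]")
  if (!is.finite(object@deadShellWidth) || object@deadShellWidth < 0)
    return("deadShellWidth must be finite and >= 0")
  TRUE
})

#' Ground-truth scene of spherical objects in a gel volume
#'
#' A virtual well: spheres (microspheres or organoids) with known centres,
#' diameters and live/dead state, suspended in a gel dome of stated depth.
#' z = 0 is the gel bottom; all lengths are in micrometres.
#'
#' @slot objects data.frame with one row per object, columns id, x, y, z,
#'   diameter (live-core diameter), live_fraction, labeled, green_intensity,
#'   red_intensity, shell_width (dead-cell annulus outside the core).
#' @slot gelDepth gel depth in micrometres.
#' @slot xyExtent numeric length-2, lateral extent (width, height) in
#'   micrometres.
#' @slot density objects per microlitre, derived from count and volume.
#' @slot seed integer seed the scene was generated with (NA when assembled
#'   by hand).
#' @seealso [generateScene()]
#' @export
setClass("Scene", representation(
  objects = "data.frame", gelDepth = "numeric", xyExtent = "numeric",
  density = "numeric", seed = "integer"
))

setValidity("Scene", function(object) {
  ob <- object@objects
  if (!all(.sceneCols %in% names(ob)))
    return(paste("objects must have columns:", paste(.sceneCols, collapse = ", ")))
  if (length(object@xyExtent) != 2L || any(object@xyExtent <= 0))
    return("xyExtent must be two positive lengths")
  if (object@gelDepth <= 0) return("gelDepth must be > 0")
  if (nrow(ob)) {
    if (any(ob$diameter <= 0)) return("all diameters must be > 0")
    if (any(ob$live_fraction < 0 | ob$live_fraction > 1))
      return("live_fraction must be in [0, 1]")
    if (any(ob$z < 0 | ob$z > object@gelDepth))
      return("object z must lie in [0, gelDepth]")
    if (any(ob$x < 0 | ob$x > object@xyExtent[1]) ||
        any(ob$y < 0 | ob$y > object@xyExtent[2]))
      return("object x/y must lie inside xyExtent")
    if (any(!ob$labeled & ob$green_intensity != 0))
      return("unlabeled objects must have green_intensity == 0")
    if (any(ob$shell_width < 0)) return("shell_width must be >= 0")
  }
  TRUE
})

#' Z-stack acquisition plan
#'
#' Focal-plane geometry of a z-stack scan: the axial range, the number of
#' layers, the (optionally rounded) step between consecutive planes, and the
#' resulting plane positions, anchored at z = 0 (gel bottom).
#'
#' @slot zRange axial scan range in micrometres.
#' @slot nLayers number of focal planes (>= 1).
#' @slot step distance between consecutive planes, micrometres (0 for a
#'   single-plane scan).
#' @slot layerPositions plane z positions in micrometres, strictly increasing.
#' @seealso [planZStack()]
#' @export
setClass("AcquisitionPlan", representation(
  zRange = "numeric", nLayers = "integer", step = "numeric",
  layerPositions = "numeric"
))

setValidity("AcquisitionPlan", function(object) {
  if (object@nLayers < 1L) return("nLayers must be >= 1")
  if (length(object@layerPositions) != object@nLayers)
    return("layerPositions length must equal nLayers")
  if (object@nLayers > 1L) {
    d <- diff(object@layerPositions)
    if (any(d <= 0)) return("layerPositions must be strictly increasing")
    if (max(abs(d - object@step)) > 1e-9)
      return("layerPositions spacing must equal step")
  }
  TRUE
})

#' Multi-channel z-stack image
#'
#' Pixel data for one field of view: rows x columns x channels x layers, with
#' physical calibration. Intensities live in [0, 1]; rendered stacks sit on
#' the 16-bit grid (k/65535) so that TIFF round trips are lossless.
#'
#' @slot pixels 4-d numeric array, dim (row, col, channel, layer).
#' @slot pixelSize micrometres per pixel.
#' @slot layerPositions focal-plane z positions (micrometres), one per layer,
#'   strictly increasing.
#' @slot channelNames character, one name per channel.
#' @seealso [renderStack()], [readStack()], [writeStack()]
#' @export
setClass("ImageStack", representation(
  pixels = "array", pixelSize = "numeric", layerPositions = "numeric",
  channelNames = "character"
))

setValidity("ImageStack", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 4L) return("pixels must be a 4-d array (row, col, channel, layer)")
  if (d[3] != length(object@channelNames))
    return("third dim of pixels must match channelNames")
  if (d[4] != length(object@layerPositions))
    return("fourth dim of pixels must match layerPositions")
  if (length(object@layerPositions) > 1 && any(diff(object@layerPositions) <= 0))
    return("layerPositions must be strictly increasing")
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (any(object@pixels < 0)) return("intensities must be >= 0")
  TRUE
})

#' All-in-focus composite of a z-stack
#'
#' Result of extended-depth-of-field fusion: one image per channel, each pixel
#' taken from the layer where the reference channel was sharpest, plus the
#' per-pixel layer index map (0-based) and the fusion provenance.
#'
#' @slot pixels 3-d numeric array, dim (row, col, channel).
#' @slot indexMap integer matrix of source layer indices, 0-based.
#' @slot pixelSize micrometres per pixel.
#' @slot channelNames character, one per channel.
#' @slot provenance list of fusion settings (reference channel, focus window,
#'   smoothing radius, layer positions).
#' @seealso [fuseStack()]
#' @export
setClass("CompositeImage", representation(
  pixels = "array", indexMap = "matrix", pixelSize = "numeric",
  channelNames = "character", provenance = "list"
))

setValidity("CompositeImage", function(object) {
  d <- dim(object@pixels)
  if (length(d) != 3L) return("pixels must be (row, col, channel)")
  if (d[3] != length(object@channelNames))
    return("third dim of pixels must match channelNames")
  if (!identical(dim(object@indexMap), d[1:2]))
    return("indexMap must match image rows/cols")
  nl <- object@provenance$n_layers
  if (!is.null(nl) && nrow(object@indexMap) &&
      (min(object@indexMap) < 0 || max(object@indexMap) >= nl))
    return("indexMap entries must be in [0, n_layers)")
  TRUE
})

#' Per-well summary of detected objects
#'
#' Aggregates over the object records of one well: count, total
#' cross-sectional area, labeling rate, overlap rate and mean gel background.
#' Rates not computed for a given well are NA.
#'
#' @slot nObjects number of detected objects.
#' @slot totalArea sum of object areas, square micrometres.
#' @slot labelingRate percent of objects above the green threshold (NA if not
#'   computed).
#' @slot overlapRate percent of objects overlapping another (NA if not
#'   computed).
#' @slot backgroundMean mean gel background intensity (NA if not computed).
#' @slot records data.frame of per-object records (see [segmentObjects()]).
#' @seealso [wellSummary()]
#' @export
setClass("WellSummary", representation(
  nObjects = "integer", totalArea = "numeric", labelingRate = "numeric",
  overlapRate = "numeric", backgroundMean = "numeric", records = "data.frame"
))

setValidity("WellSummary", function(object) {
  for (r in c(object@labelingRate, object@overlapRate))
    if (!is.na(r) && (r < 0 || r > 100)) return("rates must be in [0, 100]")
  if (object@nObjects < 0L) return("nObjects must be >= 0")
  if (nrow(object@records) &&
      abs(object@totalArea - sum(object@records$area_um2)) >
        1e-6 * max(1, object@totalArea))
    return("totalArea must equal the sum of record areas")
  TRUE
})

#' Paired day-0 / day-N summaries of one well
#'
#' @slot d0 [WellSummary-class] at treatment start.
#' @slot dN [WellSummary-class] at the follow-up day.
#' @slot day follow-up day index (> 0), metadata only.
#' @seealso [survivalRate()], [sizeChangeRatio()]
#' @export
setClass("TimepointPair", representation(
  d0 = "WellSummary", dN = "WellSummary", day = "integer"
))

setValidity("TimepointPair", function(object) {
  if (object@day <= 0L) return("day must be > 0")
  TRUE
})

#' Chemosensitivity call
#'
#' Result of thresholding the size-change ratio against the configured cutoff
#' (default 36.42 percent): ratios below the cutoff are called sensitive,
#' ratios at or above it resistant.
#'
#' @slot sizeChangeRatio percent size change (dayN / day0 area x 100).
#' @slot cutoff decision boundary in percent.
#' @slot call "sensitive" or "resistant".
#' @seealso [classifyChemosensitivity()]
#' @export
setClass("ChemoCall", representation(
  sizeChangeRatio = "numeric", cutoff = "numeric", call = "character"
))

setValidity("ChemoCall", function(object) {
  if (!object@call %in% c("sensitive", "resistant"))
    return("call must be 'sensitive' or 'resistant'")
  expected <- if (object@sizeChangeRatio < object@cutoff) "sensitive" else "resistant"
  if (object@call != expected)
    return("call must be determined by sizeChangeRatio vs cutoff")
  TRUE
})
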