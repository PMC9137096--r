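#' Construct an optical model
#'
#' Defaults describe the simulated plate scanner: 2 um/px sampling, blur
#' growing at 0.05 um of Gaussian sigma per um of defocus beyond the
#' depth-of-field band, a detectability half-depth of 80 um, detector noise of
#' 0.01 on the [0, 1] intensity scale, and a baseline background of 0.02.
#'
#' The half-depth is the optical knob behind capture efficiency: a sphere of
#' radius r is picked up by a focal plane when its centre lies within r + h of
#' it. With h = 80 um, a 7-layer scan over an 1100 um gel (180 um step)
#' captures essentially all 20 um spheres.
#'
#' @param pixelSize um per pixel.
#' @param blurCoeff um of Gaussian sigma per um of defocus beyond the
#'   depth-of-field half-depth.
#' @param dofHalfDepth detectability half-depth h, um.
#' @param noiseSd additive Gaussian noise sd (intensity units).
#' @param backgroundBase baseline background intensity B0.
#' @return an [OpticalModel-class].
#' @export
#' @examples
#' opticalModel(pixelSize = 1)
opticalModel <- function(pixelSize = 2, blurCoeff = 0.05, dofHalfDepth = 80,
                         noiseSd = 0.01, backgroundBase = 0.02) {
  new("OpticalModel", pixelSize = pixelSize, blurCoeff = blurCoeff,
      dofHalfDepth = dofHalfDepth, noiseSd = noiseSd,
      backgroundBase = backgroundBase)
}

#' Construct a staining model
#'
#' Saturating Calcein-AM labeling kinetics: a live object is labeled with
#' probability p = min(1, c * t / K). The default K = 120 uM*min makes the
#' standard staining condition (2 uM for 60 min) exactly saturating, i.e.
#' a 100 percent labeling rate. The nonspecific green gel background grows
#' linearly with staining time and is suppressed multiplicatively by Cu2+,
#' vanishing at the working quencher concentration of 0.1 mM.
#'
#' @param concentration dye concentration, uM.
#' @param time staining time, minutes.
#' @param saturationK saturation constant K, uM*min.
#' @param cuConcentration Cu2+ quencher concentration, mM.
#' @param backgroundRate gel background intensity gained per minute without
#'   quencher.
#' @param quenchReference Cu2+ concentration (mM) giving full quench.
#' @return a [StainingModel-class].
#' @export
#' @examples
#' stainingModel(concentration = 2, time = 60)   # saturating condition
stainingModel <- function(concentration = 2, time = 60, saturationK = 120,
                          cuConcentration = 0, backgroundRate = 0.002,
                          quenchReference = 0.1) {
  new("StainingModel", concentration = concentration, time = time,
      saturationK = saturationK, cuConcentration = cuConcentration,
      backgroundRate = backgroundRate, quenchReference = quenchReference)
}

#' Labeling probability of a staining model
#'
#' @param staining a [StainingModel-class].
#' @return p = min(1, c * t / K) in [0, 1].
#' @export
#' @examples
#' labelingProbability(stainingModel(1, 60))  # 0.5
labelingProbability <- function(staining) {
  stopifnot(is(staining, "StainingModel"))
  if (staining@saturationK == 0) return(1)
  min(1, staining@concentration * staining@time / staining@saturationK)
}

#' Green gel-background intensity of a staining model
#'
#' B(t) = B0 + beta * t * max(0, 1 - cu / quenchReference).
#'
#' @param staining a [StainingModel-class].
#' @param optics an [OpticalModel-class] supplying the baseline B0.
#' @return background intensity.
#' @export
gelBackground <- function(staining, optics = opticalModel()) {
  stopifnot(is(staining, "StainingModel"), is(optics, "OpticalModel"))
  quench <- if (staining@quenchReference > 0)
    max(0, 1 - staining@cuConcentration / staining@quenchReference) else 1
  optics@backgroundBase + staining@backgroundRate * staining@time * quench
}

#' Construct a treatment effect
#'
#' @param killFraction fraction in [0, 1] of objects fully killed.
#' @param shrinkFactor live-core diameter multiplier in [0, 1] for survivors.
#' @param deadShellWidth width (um) of the dead-cell annulus around survivors.
#' @return a [TreatmentEffect-class].
#' @export
#' @examples
#' treatmentEffect(killFraction = 0.5)
treatmentEffect <- function(killFraction = 0, shrinkFactor = 1,
                            deadShellWidth = 0) {
  new("TreatmentEffect", killFraction = killFraction,
      shrinkFactor = shrinkFactor, deadShellWidth = deadShellWidth)
}

#' Assemble a per-well summary from object records
#'
#' @param records data.frame of per-object records as returned by
#'   [segmentObjects()] (may have zero rows).
#' @param labelingRate,overlapRate,backgroundMean optional precomputed
#'   readouts in percent / intensity units; NA when not measured.
#' @return a [WellSummary-class].
#' @export
wellSummary <- function(records = emptyRecords(), labelingRate = NA_real_,
                        overlapRate = NA_real_, backgroundMean = NA_real_) {
  new("WellSummary",
      nObjects = nrow(records),
      totalArea = if (nrow(records)) sum(records$area_um2) else 0,
      labelingRate = labelingRate, overlapRate = overlapRate,
      backgroundMean = backgroundMean, records = records)
}

#' Pair day-0 and day-N well summaries
#'
#' @param d0 [WellSummary-class] at treatment start.
#' @param dN [WellSummary-class] at follow-up.
#' @param day follow-up day index (> 0).
#' @return a [TimepointPair-class].
#' @export
timepointPair <- function(d0, dN, day = 10L) {
  new("TimepointPair", d0 = d0, dN = dN, day = as.integer(day))
}

#' Empty per-object record table
#'
#' @return zero-row data.frame with the standard record columns.
#' @export
emptyRecords <- function() {
  data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
             area_um2 = numeric(), short_diameter_um = numeric(),
             mean_green = numeric(), mean_red = numeric(), live = logical())
}
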