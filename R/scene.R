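#' Generate a ground-truth scene of spheres in a gel volume
#'
#' Places `nObjects` spheres uniformly at random in a gel dome of depth
#' `gelDepth` and lateral extent `xyExtent`, emulating microspheres or
#' organoids resuspended in a Matrigel droplet. Objects start fully live,
#' unlabeled, and without a dead shell. Centres are kept at least one radius
#' away from the lateral borders so every object's footprint lies inside the
#' field; z is unrestricted within [0, gelDepth] (spheres may protrude past
#' the gel top/bottom, as they do at a real dome boundary).
#'
#' @param nObjects number of objects (>= 0).
#' @param diameter either a single diameter in um, a vector of diameters to
#'   sample from uniformly, or a function(n) returning n diameters.
#' @param gelDepth gel depth in um (default the 1100 um dome used throughout).
#' @param xyExtent lateral extent in um, length-2 (width, height) or a single
#'   value for a square field.
#' @param seed integer seed; identical seeds and parameters reproduce the
#'   scene exactly.
#' @return a [Scene-class]; its `density` is the object count per uL of the
#'   stated volume.
#' @export
#' @examples
#' sc <- generateScene(100, diameter = 20, seed = 1)
#' sceneDensity(sc)
generateScene <- function(nObjects, diameter = 20, gelDepth = 1100,
                          xyExtent = c(3000, 3000), seed = NULL) {
  stopIfNot(is.numeric(nObjects) && length(nObjects) == 1L &&
              nObjects >= 0 && nObjects == round(nObjects),
            "nObjects must be a single non-negative integer")
  stopIfNot(is.numeric(gelDepth) && gelDepth > 0, "gelDepth must be > 0")
  if (length(xyExtent) == 1L) xyExtent <- rep(xyExtent, 2L)
  stopIfNot(length(xyExtent) == 2L && all(xyExtent > 0),
            "xyExtent must be one or two positive lengths")
  n <- as.integer(nObjects)

  diams <- withSeed(seed, {
    d <- if (is.function(diameter)) diameter(n)
         else if (length(diameter) == 1L) rep(as.numeric(diameter), n)
         else sample(as.numeric(diameter), n, replace = TRUE)
    stopIfNot(length(d) == n && all(d > 0), "diameters must be positive")
    r <- d / 2
    stopIfNot(all(2 * r < xyExtent[1]) && all(2 * r < xyExtent[2]),
              "objects larger than the lateral extent")
    data.frame(
      id = seq_len(n),
      x = r + runif(n) * (xyExtent[1] - 2 * r),
      y = r + runif(n) * (xyExtent[2] - 2 * r),
      z = runif(n, 0, gelDepth),
      diameter = d,
      live_fraction = rep(1, n),
      labeled = rep(FALSE, n),
      green_intensity = rep(0, n),
      red_intensity = rep(0, n),
      shell_width = rep(0, n)
    )
  })

  volume_uL <- xyExtent[1] * xyExtent[2] * gelDepth / 1e9  # um^3 -> uL
  new("Scene", objects = diams, gelDepth = gelDepth,
      xyExtent = as.numeric(xyExtent), density = n / volume_uL,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

#' Apply staining kinetics to a scene
#'
#' Each object with a positive live fraction is labeled independently with
#' probability p = min(1, c * t / K); labeled objects receive a green
#' intensity proportional to their live fraction. Objects with a positive dead
#' compartment (dead shell or zero live fraction) carry red intensity from the
#' membrane-impermeant dead stain.
#'
#' @param scene a [Scene-class].
#' @param staining a [StainingModel-class].
#' @param seed integer seed for the independent labeling draws.
#' @return the scene with `labeled`, `green_intensity` and `red_intensity`
#'   updated.
#' @export
#' @examples
#' sc <- generateScene(10, seed = 1)
#' sc <- applyStaining(sc, stainingModel(2, 60), seed = 2)  # saturating: all labeled
setMethod("applyStaining", signature("Scene", "StainingModel"),
  function(scene, staining, seed = NULL) {
    ob <- scene@objects
    if (nrow(ob)) {
      p <- labelingProbability(staining)
      lab <- withSeed(seed, runif(nrow(ob)) < p) & ob$live_fraction > 0
      ob$labeled <- lab
      ob$green_intensity <- ifelse(lab, ob$live_fraction, 0)
      ## PI marks the dead compartment regardless of the live dye dose
      ob$red_intensity <- ifelse(ob$live_fraction == 0 | ob$shell_width > 0, 1, ob$red_intensity)
      scene@objects <- ob
    }
    validObject(scene)
    scene
  })

#' Apply a treatment effect to a scene
#'
#' A `killFraction` share of objects, drawn independently, is fully killed:
#' live fraction drops to zero, the body red-stains, and any previous green
#' label is lost. Survivors keep a live core shrunken by `shrinkFactor`
#' (diameter multiplier) surrounded by a loose dead-cell shell of width
#' `deadShellWidth`, mirroring the post-treatment morphology of a live core
#' inside scattered dead cells.
#'
#' @param scene a [Scene-class].
#' @param effect a [TreatmentEffect-class].
#' @param seed integer seed for the independent kill draws.
#' @return the treated scene.
#' @export
#' @examples
#' sc <- generateScene(10, seed = 1)
#' applyTreatment(sc, treatmentEffect(0.5, 0.6, 10), seed = 2)
setMethod("applyTreatment", signature("Scene", "TreatmentEffect"),
  function(scene, effect, seed = NULL) {
    ob <- scene@objects
    if (nrow(ob)) {
      killed <- withSeed(seed, runif(nrow(ob)) < effect@killFraction)
      ob$live_fraction[killed] <- 0
      ob$red_intensity[killed] <- 1
      ob$green_intensity[killed] <- 0
      ob$labeled[killed] <- FALSE
      surv <- !killed
      ob$diameter[surv] <- pmax(ob$diameter[surv] * effect@shrinkFactor,
                                .Machine$double.eps)
      ob$shell_width[surv] <- ob$shell_width[surv] + effect@deadShellWidth
      if (effect@deadShellWidth > 0) ob$red_intensity[surv] <- 1
      scene@objects <- ob
    }
    validObject(scene)
    scene
  })

## total footprint radius in the brightfield channel: live core + dead shell
.footprintRadius <- function(objects) objects$diameter / 2 + objects$shell_width
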