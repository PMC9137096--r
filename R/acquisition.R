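#' Plan a z-stack scan
#'
#' Lays `nLayers` focal planes over an axial range of `zRange` micrometres,
#' anchored at z = 0 (the gel bottom). For two or more layers the step is
#' zRange / (nLayers - 1), rounded to the nearest `roundTo` micrometres (the
#' granularity a stage controller is driven at); planes sit at 0, step,
#' 2*step, ... A single-layer scan places its lone plane mid-range.
#'
#' With the 1100 um gel dome used throughout, 7 layers give the 180 um step
#' of the reference scan design.
#'
#' @param zRange axial range, um (> 0).
#' @param nLayers number of focal planes (>= 1).
#' @param roundTo step rounding granularity in um; 0 disables rounding.
#' @return an [AcquisitionPlan-class].
#' @export
#' @examples
#' planZStack(1100, 7)         # step 180 um
#' planZStack(1100, 7, roundTo = 0)  # exact 183.33 um step
planZStack <- function(zRange, nLayers, roundTo = 10) {
  stopIfNot(is.numeric(zRange) && length(zRange) == 1L && zRange > 0,
            "zRange must be a single positive length")
  stopIfNot(is.numeric(nLayers) && length(nLayers) == 1L &&
              nLayers >= 1 && nLayers == round(nLayers),
            "nLayers must be a single integer >= 1")
  n <- as.integer(nLayers)
  if (n == 1L) {
    step <- 0
    pos <- zRange / 2
  } else {
    step <- zRange / (n - 1)
    if (roundTo > 0) step <- round(step / roundTo) * roundTo
    stopIfNot(step > 0, "rounded step collapsed to 0; lower roundTo")
    pos <- step * (seq_len(n) - 1)
  }
  new("AcquisitionPlan", zRange = zRange, nLayers = n, step = step,
      layerPositions = pos)
}

#' Closed-form capture efficiency of a scan plan
#'
#' Expected fraction of spheres of a given diameter, placed uniformly along z,
#' that are detectable in at least one focal plane. A sphere of radius r is
#' detectable in a plane when its centre lies within r + h of it (h the
#' optical detectability half-depth), so each plane captures a band of
#' 2*(r + h) and the captured fraction is min(1, 2*(r + h) / step). For a
#' single-plane scan the lone band is referred to the full axial range.
#'
#' @param diameter sphere diameter, um (> 0); vectorised.
#' @param plan an [AcquisitionPlan-class].
#' @param optics an [OpticalModel-class] (supplies h).
#' @return capture fraction(s) in [0, 1].
#' @export
#' @examples
#' captureEfficiencyClosedForm(20, planZStack(1100, 7))  # 1
captureEfficiencyClosedForm <- function(diameter, plan, optics = opticalModel()) {
  stopIfNot(all(diameter > 0), "diameter must be > 0")
  reach <- diameter / 2 + optics@dofHalfDepth
  denom <- if (plan@nLayers == 1L || plan@step == 0) plan@zRange else plan@step
  pmin(1, 2 * reach / denom)
}

## Monte-Carlo capture fraction at the geometry level: uniform z placement,
## captured when the nearest plane is within r + h. The cheap oracle against
## which the closed form and the full imaging path are both checked.
.captureMC <- function(diameter, plan, optics, nSim, seed) {
  reach <- diameter / 2 + optics@dofHalfDepth
  withSeed(seed, {
    z <- stats::runif(nSim, 0, plan@zRange)
    dmin <- vapply(z, function(zi) min(abs(zi - plan@layerPositions)), 0)
    mean(dmin <= reach)
  })
}

#' Empirical capture efficiency through the full imaging pipeline
#'
#' Renders the scene tile by tile, fuses each tile's z-stack into an
#' all-in-focus composite, segments the brightfield composite, and returns the
#' ratio of detected to true object count. Tiles are rendered with a guard
#' margin and only detections whose centroid falls in the tile core are
#' counted, so objects straddling tile borders are counted exactly once.
#'
#' The minimum-area filter passed to segmentation defaults to half the nominal
#' cross-section of the smallest planted diameter: when measuring capture of a
#' known size class, the filter must not reject that class.
#'
#' @param scene a non-empty [Scene-class].
#' @param plan an [AcquisitionPlan-class].
#' @param optics an [OpticalModel-class].
#' @param seed integer seed (per-tile noise streams are derived from it).
#' @param fieldPx tile (field of view) size in pixels.
#' @param minArea minimum object area in um2 passed to [segmentObjects()];
#'   NULL for the planted-size default.
#' @param window,smooth EDF fusion settings, see [fuseStack()].
#' @return the captured fraction (detected / true), with attributes
#'   `detected`, `true`, and `flag_overdetection` (TRUE when detections exceed
#'   ground truth, a merging/splitting artifact worth inspecting).
#' @export
captureEfficiencyEmpirical <- function(scene, plan, optics = opticalModel(),
                                       seed = NULL, fieldPx = 512,
                                       minArea = NULL, window = 4, smooth = 2) {
  stopifnot(is(scene, "Scene"))
  ob <- scene@objects
  stopIfNot(nrow(ob) > 0, "scene must contain at least one object")
  if (is.null(minArea))
    minArea <- 0.5 * pi * (min(ob$diameter) / 2)^2
  ps <- optics@pixelSize
  tileUm <- fieldPx * ps
  margin <- max(.footprintRadius(ob)) + 10
  ntx <- max(1L, ceiling(scene@xyExtent[1] / tileUm))
  nty <- max(1L, ceiling(scene@xyExtent[2] / tileUm))
  detected <- 0L
  tile <- 0L
  for (ty in seq_len(nty)) for (tx in seq_len(ntx)) {
    tile <- tile + 1L
    x0 <- (tx - 1) * tileUm; x1 <- min(tx * tileUm, scene@xyExtent[1])
    y0 <- (ty - 1) * tileUm; y1 <- min(ty * tileUm, scene@xyExtent[2])
    keep <- ob$x >= x0 - margin & ob$x <= x1 + margin &
            ob$y >= y0 - margin & ob$y <= y1 + margin
    if (!any(keep)) next
    sub <- ob[keep, , drop = FALSE]
    sub$x <- sub$x - (x0 - margin)
    sub$y <- sub$y - (y0 - margin)
    subScene <- new("Scene", objects = sub, gelDepth = scene@gelDepth,
                    xyExtent = c(x1 - x0, y1 - y0) + 2 * margin,
                    density = scene@density, seed = NA_integer_)
    st <- renderStack(subScene, plan, optics, channels = "brightfield",
                      seed = if (is.null(seed)) NULL else seed + tile)
    comp <- fuseStack(st, referenceChannel = "brightfield",
                      window = window, smooth = smooth)
    seg <- segmentObjects(comp, channel = "brightfield", minArea = minArea)
    rec <- seg$records
    if (nrow(rec)) {
      inCore <- rec$x_um >= margin & rec$x_um < margin + (x1 - x0) &
                rec$y_um >= margin & rec$y_um < margin + (y1 - y0)
      detected <- detected + sum(inCore)
    }
  }
  frac <- detected / nrow(ob)
  structure(frac, detected = detected, true = nrow(ob),
            flag_overdetection = detected > nrow(ob))
}

#' Capture-efficiency curves over diameters and layer counts
#'
#' Tabulates the captured fraction of uniformly placed spheres for every
#' combination of diameter and layer count, either in closed form or by
#' geometry-level Monte Carlo against the actual (rounded) plane positions.
#' Because detected objects present their full equatorial cross-section in the
#' fused composite, the captured area fraction equals the captured count
#' fraction; both columns are reported for symmetry with per-well outputs.
#'
#' @param diameters vector of sphere diameters, um.
#' @param layerCounts vector of layer counts.
#' @param zRange axial scan range, um.
#' @param optics an [OpticalModel-class].
#' @param mode "closed_form" or "empirical" (Monte Carlo, `nSim` placements
#'   per cell).
#' @param nSim Monte-Carlo placements per cell.
#' @param seed integer seed for the Monte-Carlo mode.
#' @param roundTo step rounding passed to [planZStack()].
#' @return data.frame with columns diameter_um, n_layers, step_um, frac_count,
#'   frac_area.
#' @export
#' @examples
#' captureCurve(c(10, 20, 100), c(2, 7, 14))
captureCurve <- function(diameters, layerCounts, zRange = 1100,
                         optics = opticalModel(),
                         mode = c("closed_form", "empirical"),
                         nSim = 2000, seed = NULL, roundTo = 10) {
  mode <- match.arg(mode)
  stopIfNot(length(diameters) >= 1 && length(layerCounts) >= 1,
            "diameters and layerCounts must be non-empty")
  grid <- expand.grid(diameter_um = as.numeric(diameters),
                      n_layers = as.integer(layerCounts))
  grid <- grid[order(grid$diameter_um, grid$n_layers), , drop = FALSE]
  rownames(grid) <- NULL
  res <- mapply(function(d, n) {
    plan <- planZStack(zRange, n, roundTo = roundTo)
    f <- if (mode == "closed_form")
      captureEfficiencyClosedForm(d, plan, optics)
    else
      .captureMC(d, plan, optics, nSim,
                 seed = if (is.null(seed)) NULL
                        else seed + 1000L * match(d, diameters) + n)
    c(step = plan@step, frac = f)
  }, grid$diameter_um, grid$n_layers)
  grid$step_um <- res["step", ]
  grid$frac_count <- res["frac", ]
  grid$frac_area <- res["frac", ]
  grid
}
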