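## Rasterisation helpers -----------------------------------------------------

## Soft-edged disk/annulus coverage on a local pixel grid. Distances are in
## pixels; coverage ramps linearly over one pixel around the rim, a cheap
## area-accurate anti-aliasing.
.diskCoverage <- function(dist, rOuter, rInner = 0) {
  cov <- pmin(1, pmax(0, rOuter - dist + 0.5))
  if (rInner > 0) cov <- cov - pmin(1, pmax(0, rInner - dist + 0.5))
  dim(cov) <- dim(dist)  # pmin/pmax drop the matrix shape
  cov
}

## Add one (possibly blurred) disk or annulus into `canvas` (row, col matrix).
## cx/cy are object centre coordinates in um; radii in um; sigma in um.
.drawObject <- function(canvas, cx, cy, rOuter, amplitude, pixelSize,
                        sigma = 0, rInner = 0) {
  if (amplitude <= 0 || rOuter <= 0) return(canvas)
  rpx <- rOuter / pixelSize
  ripx <- rInner / pixelSize
  spx <- sigma / pixelSize
  pad <- ceiling(rpx + 4 * spx + 2)
  ## pixel centres: pixel (i, j), 1-based, sits at ((j-0.5), (i-0.5)) * pixelSize
  jc <- cx / pixelSize + 0.5
  ic <- cy / pixelSize + 0.5
  i0 <- floor(ic) - pad; i1 <- floor(ic) + pad
  j0 <- floor(jc) - pad; j1 <- floor(jc) + pad
  ii <- i0:i1; jj <- j0:j1
  di <- ii - ic; dj <- jj - jc
  dist <- sqrt(outer(di^2, dj^2, `+`))
  patch <- amplitude * .diskCoverage(dist, rpx, ripx)
  if (spx > 0.3)
    patch <- EBImage::imageData(EBImage::gblur(EBImage::Image(patch), sigma = spx))
  ## clip patch to canvas and accumulate
  nr <- nrow(canvas); nc <- ncol(canvas)
  ki <- which(ii >= 1 & ii <= nr); kj <- which(jj >= 1 & jj <= nc)
  if (length(ki) && length(kj))
    canvas[ii[ki], jj[kj]] <- canvas[ii[ki], jj[kj]] + patch[ki, kj]
  canvas
}

## Per-object rendering geometry at one focal plane. An object is visible when
## its centre is within footprintRadius + dofHalfDepth of the plane; blur sets
## in only beyond the depth-of-field band.
.objectAtPlane <- function(objects, zPlane, optics) {
  dz <- abs(objects$z - zPlane)
  rTot <- .footprintRadius(objects)
  visible <- dz <= rTot + optics@dofHalfDepth
  sigma <- optics@blurCoeff * pmax(0, dz - optics@dofHalfDepth)
  list(visible = visible, sigma = sigma)
}

#' Render a scene into a multi-channel z-stack
#'
#' Simulates the acquisition of one field of view: at every focal plane each
#' visible object is drawn as a disk of its equatorial cross-section,
#' Gaussian-blurred according to its defocus, on top of channel-specific
#' background, with additive detector noise. Channels:
#' \describe{
#'   \item{brightfield}{every object's full footprint (live core plus dead
#'     shell), fixed contrast.}
#'   \item{green}{the live core of labeled objects, intensity proportional to
#'     live fraction, over the gel autofluorescence background
#'     B(t) = B0 + beta*t*max(0, 1 - cu/0.1) set by `staining`.}
#'   \item{red}{the dead compartment: the whole body of killed objects, the
#'     shell annulus of treated survivors.}
#' }
#'
#' Visibility follows the optical model's detectability half-depth h: an
#' object of footprint radius r is rendered in a plane when its centre lies
#' within r + h of it, sharp while within h, and blurred with
#' sigma = blurCoeff * (defocus - h) beyond. Intensities are clamped to
#' [0, 1] (detector saturation) and quantised to the 16-bit camera grid so the
#' stack round-trips TIFF losslessly. Identical seeds give bit-identical
#' stacks.
#'
#' @param scene a [Scene-class].
#' @param plan an [AcquisitionPlan-class]; a warning is raised when its range
#'   exceeds the scene's gel depth (objects are still rendered where the
#'   optics permit).
#' @param optics an [OpticalModel-class].
#' @param channels character subset of c("brightfield", "green", "red").
#' @param staining a [StainingModel-class]; only its time/quencher matter here
#'   (green background). Labeling itself is applied with [applyStaining()].
#' @param seed integer seed for the detector noise.
#' @return an [ImageStack-class].
#' @export
#' @examples
#' sc <- applyStaining(generateScene(5, 40, xyExtent = 256, seed = 1),
#'                     stainingModel(), seed = 2)
#' st <- renderStack(sc, planZStack(1100, 7), opticalModel(), seed = 3)
renderStack <- function(scene, plan, optics = opticalModel(),
                        channels = c("brightfield", "green", "red"),
                        staining = stainingModel(), seed = NULL) {
  stopifnot(is(scene, "Scene"), is(plan, "AcquisitionPlan"),
            is(optics, "OpticalModel"), is(staining, "StainingModel"))
  stopIfNot(length(channels) >= 1, "at least one channel required")
  bad <- setdiff(channels, c("brightfield", "green", "red"))
  stopIfNot(length(bad) == 0, paste("unknown channel(s):", paste(bad, collapse = ", ")))
  if (plan@zRange > scene@gelDepth + 1e-9)
    warning("acquisition z-range exceeds the scene gel depth; ",
            "out-of-gel planes are rendered anyway")

  ps <- optics@pixelSize
  nr <- ceiling(scene@xyExtent[2] / ps)
  nc <- ceiling(scene@xyExtent[1] / ps)
  nch <- length(channels)
  nl <- plan@nLayers
  ob <- scene@objects
  rCore <- ob$diameter / 2
  rTot <- .footprintRadius(ob)
  bgGreen <- gelBackground(staining, optics)
  bfAmplitude <- 0.8

  pix <- array(0, dim = c(nr, nc, nch, nl))
  for (l in seq_len(nl)) {
    geo <- .objectAtPlane(ob, plan@layerPositions[l], optics)
    idx <- which(geo$visible)
    for (c in seq_len(nch)) {
      canvas <- matrix(0, nr, nc)
      for (k in idx) {
        canvas <- switch(channels[c],
          brightfield = .drawObject(canvas, ob$x[k], ob$y[k], rTot[k],
                                    bfAmplitude, ps, geo$sigma[k]),
          green = .drawObject(canvas, ob$x[k], ob$y[k], rCore[k],
                              ob$green_intensity[k], ps, geo$sigma[k]),
          red = if (ob$live_fraction[k] == 0)
            .drawObject(canvas, ob$x[k], ob$y[k], rTot[k],
                        ob$red_intensity[k], ps, geo$sigma[k])
          else
            .drawObject(canvas, ob$x[k], ob$y[k], rTot[k],
                        ob$red_intensity[k], ps, geo$sigma[k], rInner = rCore[k])
        )
      }
      bg <- switch(channels[c], brightfield = optics@backgroundBase,
                   green = bgGreen, red = optics@backgroundBase)
      pix[, , c, l] <- canvas + bg
    }
  }
  if (optics@noiseSd > 0)
    pix <- pix + withSeed(seed, array(stats::rnorm(length(pix), 0, optics@noiseSd),
                                      dim = dim(pix)))
  pix <- pmin(1, pmax(0, pix))   # detector saturation; pmin/pmax drop dims
  dim(pix) <- c(nr, nc, nch, nl)
  pix <- quantize16(pix)
  new("ImageStack", pixels = pix, pixelSize = ps,
      layerPositions = as.numeric(plan@layerPositions),
      channelNames = as.character(channels))
}
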