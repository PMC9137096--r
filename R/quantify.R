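## minimum Feret diameter (the "short diameter") of a set of 2-d points via
## rotating calipers on the convex hull: the smallest width over all
## orientations equals, for some hull edge, the farthest point's distance to
## that edge's line.
.minFeret <- function(x, y) {
  if (length(x) < 2L) return(0)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  nh <- length(h)
  if (nh < 2L) return(0)
  if (nh == 2L) return(0)  # collinear: zero width
  best <- Inf
  for (i in seq_len(nh)) {
    j <- if (i == nh) 1L else i + 1L
    ex <- hx[j] - hx[i]; ey <- hy[j] - hy[i]
    len <- sqrt(ex^2 + ey^2)
    if (len == 0) next
    width <- max(abs((hx - hx[i]) * ey - (hy - hy[i]) * ex)) / len
    if (width < best) best <- width
  }
  if (is.finite(best)) best else 0
}

#' Segment objects in a composite image and measure them
#'
#' Standard pipeline for round objects on a darker background: Otsu threshold
#' on the chosen channel, hole filling, distance-transform watershed to split
#' touching objects (local-maximum suppression of 2 px), and removal of
#' components below the minimum area. Each surviving label is measured: area,
#' centroid, short diameter (minimum Feret diameter of the footprint), and
#' mean green/red intensity if those channels are present.
#'
#' The default minimum area is the cross-section of a 20 um circle
#' (~314 um2), the smallest size class treated as a real object; smaller
#' components are considered debris.
#'
#' @param composite a [CompositeImage-class].
#' @param channel channel to segment (default brightfield).
#' @param minArea minimum object area in um2.
#' @param greenThreshold mean-green intensity above which an object is called
#'   live.
#' @return list with `labels` (integer label matrix, 0 = background) and
#'   `records` (data.frame: id, x_um, y_um, area_um2, short_diameter_um,
#'   mean_green, mean_red, live). A blank image yields zero records.
#' @export
segmentObjects <- function(composite, channel = "brightfield", minArea = 314,
                           greenThreshold = defaultGreenThreshold()) {
  stopifnot(is(composite, "CompositeImage"))
  stopIfNot(minArea >= 0, "minArea must be >= 0")
  img <- getChannel(composite, channel)
  ps <- composite@pixelSize
  blank <- list(labels = matrix(0L, nrow(img), ncol(img)), records = emptyRecords())

  rng <- range(img)
  if (diff(rng) < 1e-6) return(blank)  # featureless image
  clamped <- pmin(1, pmax(0, img))
  dim(clamped) <- dim(img)
  th <- EBImage::otsu(EBImage::Image(clamped), range = c(0, 1))
  bin <- img > th
  if (!any(bin)) return(blank)
  bin <- EBImage::fillHull(bin)
  dm <- EBImage::distmap(bin)
  lab <- EBImage::watershed(dm, tolerance = 2, ext = 1)
  lab <- EBImage::imageData(lab)
  storage.mode(lab) <- "integer"

  pxArea <- ps^2
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts * pxArea >= minArea)
  if (!length(keep)) return(blank)

  ## relabel sequentially, smallest original label first (deterministic ids)
  remap <- integer(length(counts))
  remap[keep] <- seq_along(keep)
  lab[lab > 0L] <- remap[lab[lab > 0L]]

  hasG <- "green" %in% composite@channelNames
  hasR <- "red" %in% composite@channelNames
  green <- if (hasG) getChannel(composite, "green") else NULL
  red <- if (hasR) getChannel(composite, "red") else NULL

  pix <- which(lab > 0L, arr.ind = TRUE)
  lv <- lab[pix]
  ord <- order(lv)
  pix <- pix[ord, , drop = FALSE]; lv <- lv[ord]
  splitIdx <- split(seq_along(lv), lv)

  n <- length(splitIdx)
  ids <- xum <- yum <- area <- sdm <- mg <- mr <- numeric(n)
  for (k in seq_len(n)) {
    sel <- splitIdx[[k]]
    rows <- pix[sel, 1]; cols <- pix[sel, 2]
    ids[k] <- k
    ## pixel (i, j) centre sits at ((j - 0.5), (i - 0.5)) * ps
    xum[k] <- (mean(cols) - 0.5) * ps
    yum[k] <- (mean(rows) - 0.5) * ps
    area[k] <- length(sel) * pxArea
    sdm[k] <- (.minFeret(cols, rows) + 1) * ps  # + 1 px for pixel extent
    lin <- (cols - 1) * nrow(lab) + rows
    mg[k] <- if (hasG) mean(green[lin]) else 0
    mr[k] <- if (hasR) mean(red[lin]) else 0
  }
  records <- data.frame(id = as.integer(ids), x_um = xum, y_um = yum,
                        area_um2 = area, short_diameter_um = sdm,
                        mean_green = mg, mean_red = mr,
                        live = mg > greenThreshold)
  list(labels = lab, records = records)
}

#' Labeling rate: percent of objects above the green threshold
#'
#' For a record table, 100 x the fraction of objects whose mean green
#' intensity exceeds the threshold. For a [Scene-class], the same computed on
#' ground-truth object intensities. An empty well is an error, not 0 percent:
#' a labeling rate is undefined without objects.
#'
#' @param x data.frame of object records, a [Scene-class], or a
#'   [WellSummary-class].
#' @param greenThreshold intensity threshold (>= 0).
#' @param ... unused.
#' @return percent in [0, 100].
#' @name labelingRate
#' @export
#' @examples
#' sc <- applyStaining(generateScene(50, seed = 1), stainingModel(2, 60), seed = 2)
#' labelingRate(sc)   # 100
setMethod("labelingRate", "data.frame", function(x, greenThreshold = defaultGreenThreshold(), ...) {
  stopIfNot(greenThreshold >= 0, "greenThreshold must be >= 0")
  if (nrow(x) == 0L) stop("empty well: labeling rate is undefined", call. = FALSE)
  100 * mean(x$mean_green > greenThreshold)
})

#' @rdname labelingRate
setMethod("labelingRate", "Scene", function(x, greenThreshold = defaultGreenThreshold(), ...) {
  ob <- x@objects
  if (nrow(ob) == 0L) stop("empty well: labeling rate is undefined", call. = FALSE)
  100 * mean(ob$green_intensity > greenThreshold)
})

#' @rdname labelingRate
setMethod("labelingRate", "WellSummary", function(x, greenThreshold = defaultGreenThreshold(), ...) {
  if (!is.na(x@labelingRate)) return(x@labelingRate)
  labelingRate(x@records, greenThreshold)
})

#' Overlap rate of projected object footprints
#'
#' In a 2D projection of a 3D culture, objects whose xy footprints collide
#' cannot be measured independently; the overlap rate quantifies how bad this
#' gets as planting density rises.
#'
#' Ground-truth mode (on a [Scene-class]): 100 x the fraction of objects whose
#' xy-projected footprint disk intersects at least one other object's disk.
#' Detected mode (on records or a [WellSummary-class], with the true count
#' supplied): 100 x (1 - n_detected / n_true), clipped to [0, 100] -- the
#' count deficit attributable to objects merging in projection.
#'
#' @param x a [Scene-class] (ground-truth mode) or object records /
#'   [WellSummary-class] (detected mode).
#' @param mode "ground_truth" or "detected".
#' @param nTrue true object count, required in detected mode.
#' @param ... unused.
#' @return percent in [0, 100].
#' @name overlapRate
#' @export
#' @examples
#' overlapRate(generateScene(1, seed = 1))  # 0
setMethod("overlapRate", "Scene", function(x, mode = c("ground_truth", "detected"), ...) {
  mode <- match.arg(mode)
  if (mode == "detected")
    stop("detected mode needs detection records and nTrue; ",
         "call overlapRate(records, mode = 'detected', nTrue = ...)", call. = FALSE)
  ob <- x@objects
  n <- nrow(ob)
  if (n == 0L) return(0)
  if (n == 1L) return(0)
  r <- .footprintRadius(ob)
  ## sweep over x-sorted objects; only candidates within the max pair reach
  ord <- order(ob$x)
  xs <- ob$x[ord]; ys <- ob$y[ord]; rs <- r[ord]
  maxR <- max(rs)
  hit <- logical(n)
  j0 <- 1L
  for (i in seq_len(n)) {
    ## window bound must not depend on rs[i]: j0 only ever moves forward
    while (xs[i] - xs[j0] > 2 * maxR) j0 <- j0 + 1L
    for (j in j0:i) {
      if (j == i) next
      if (hit[i] && hit[j]) next
      dx <- xs[i] - xs[j]; dy <- ys[i] - ys[j]
      if (dx * dx + dy * dy < (rs[i] + rs[j])^2) { hit[i] <- TRUE; hit[j] <- TRUE }
    }
  }
  100 * mean(hit)
})

#' @rdname overlapRate
setMethod("overlapRate", "data.frame", function(x, mode = c("ground_truth", "detected"),
                                                nTrue = NULL, ...) {
  mode <- match.arg(mode)
  if (mode == "ground_truth")
    stop("ground-truth mode needs a Scene with object geometry", call. = FALSE)
  stopIfNot(!is.null(nTrue) && is.numeric(nTrue) && nTrue > 0,
            "detected mode requires the true object count nTrue")
  min(100, max(0, 100 * (1 - nrow(x) / nTrue)))
})

#' @rdname overlapRate
setMethod("overlapRate", "WellSummary", function(x, mode = c("ground_truth", "detected"),
                                                 nTrue = NULL, ...) {
  overlapRate(x@records, mode = mode, nTrue = nTrue)
})

#' Gel background intensity from diffused sample points
#'
#' Emulates the background readout taken at a handful of diffused positions in
#' cell-free gel: `nPoints` locations are spread over the background (outside
#' the exclusion mask, with a minimum mutual distance so they do not bunch),
#' each read as the mean of a patch x patch pixel neighbourhood; the reported
#' background is the mean of the point readings.
#'
#' @param image single-channel 2-d numeric matrix.
#' @param exclusionMask optional label matrix (e.g. from [segmentObjects()]);
#'   pixels with label > 0 and their patch surroundings are excluded.
#' @param nPoints number of sample points (default 9).
#' @param seed integer seed for the point placement.
#' @param patch patch side in pixels (odd; default 5).
#' @return mean background intensity.
#' @export
backgroundIntensity <- function(image, exclusionMask = NULL, nPoints = 9,
                                seed = NULL, patch = 5) {
  stopIfNot(is.matrix(image) && is.numeric(image), "image must be a numeric matrix")
  stopIfNot(nPoints >= 1, "nPoints must be >= 1")
  stopIfNot(patch >= 1 && patch %% 2 == 1, "patch must be odd and >= 1")
  half <- (patch - 1) / 2
  nr <- nrow(image); nc <- ncol(image)
  ok <- matrix(TRUE, nr, nc)
  if (!is.null(exclusionMask)) {
    stopIfNot(identical(dim(exclusionMask), dim(image)),
              "exclusionMask must match the image size")
    ## dilate the mask by the patch half-width so patches stay clean
    m <- exclusionMask > 0
    if (any(m)) {
      kern <- EBImage::makeBrush(2 * half + 1, shape = "box")
      m <- EBImage::imageData(EBImage::dilate(EBImage::Image(m * 1), kern)) > 0
    }
    ok <- !m
  }
  ## keep patches inside the frame
  valid <- which(ok &
                 row(image) > half & row(image) <= nr - half &
                 col(image) > half & col(image) <= nc - half)
  if (!length(valid))
    stop("no background available: the exclusion mask covers the image", call. = FALSE)
  withSeed(seed, {
    cand <- sample(valid)
    minDist2 <- (0.4 * sqrt(length(valid) / nPoints))^2
    repeat {
      pts <- integer(0)
      pr <- pc <- numeric(0)
      for (v in cand) {
        i <- (v - 1) %% nr + 1; j <- (v - 1) %/% nr + 1
        if (!length(pts) || all((pr - i)^2 + (pc - j)^2 >= minDist2)) {
          pts <- c(pts, v); pr <- c(pr, i); pc <- c(pc, j)
          if (length(pts) == nPoints) break
        }
      }
      if (length(pts) == nPoints || minDist2 <= 1) break
      minDist2 <- minDist2 / 4  # relax the spread if the space is too tight
    }
    if (length(pts) < nPoints)
      stop("not enough background pixels to place ", nPoints, " points", call. = FALSE)
    vals <- vapply(seq_along(pts), function(k) {
      mean(image[(pr[k] - half):(pr[k] + half), (pc[k] - half):(pc[k] + half)])
    }, 0)
    mean(vals)
  })
}

#' Histogram of short diameters
#'
#' @param records data.frame of object records.
#' @param binEdges increasing vector of bin edges in um. Values outside the
#'   range are counted in the first/last bin, so the counts always sum to the
#'   number of objects.
#' @return named integer vector of per-bin counts.
#' @export
#' @examples
#' sizeDistribution(emptyRecords(), c(0, 20, 100, 500))
sizeDistribution <- function(records, binEdges) {
  stopIfNot(length(binEdges) >= 2 && all(diff(binEdges) > 0),
            "binEdges must be increasing with at least two values")
  nb <- length(binEdges) - 1L
  labs <- paste0("[", binEdges[-length(binEdges)], ",", binEdges[-1], ")")
  if (nrow(records) == 0L)
    return(stats::setNames(integer(nb), labs))
  v <- records$short_diameter_um
  bin <- findInterval(v, binEdges, rightmost.closed = FALSE)
  bin <- pmin(pmax(bin, 1L), nb)   # clamp under/overflow into the end bins
  stats::setNames(tabulate(bin, nbins = nb), labs)
}
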