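#' Per-pixel focus measure: local variance of the Laplacian
#'
#' Sharp structure produces a strong second-derivative response; its local
#' variance within a (2*window + 1) square neighbourhood is the per-pixel
#' focus score used to decide, for every pixel, which layer of a z-stack is
#' sharpest. Blurring an image strictly lowers its focus score over
#' structured regions; a constant image scores 0 everywhere.
#'
#' @param image single-channel 2-d numeric matrix.
#' @param window neighbourhood radius in pixels (>= 1); the full window must
#'   fit inside the image.
#' @return non-negative matrix of the same size.
#' @export
#' @examples
#' img <- matrix(0, 32, 32); img[10:20, 10:20] <- 1
#' fm <- focusMeasure(img)
#' max(fm) > 0
focusMeasure <- function(image, window = 4) {
  stopIfNot(is.matrix(image) && is.numeric(image), "image must be a numeric matrix")
  stopIfNot(length(window) == 1L && window >= 1 && window == round(window),
            "window must be a single integer >= 1")
  side <- 2 * window + 1
  stopIfNot(side <= min(dim(image)),
            "window larger than the image")
  if (diff(range(image)) == 0)           # constant image: no structure at all
    return(matrix(0, nrow(image), ncol(image)))
  lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  L <- EBImage::imageData(EBImage::filter2(EBImage::Image(image), lap, boundary = "replicate"))
  box <- matrix(1 / side^2, side, side)
  m1 <- EBImage::imageData(EBImage::filter2(EBImage::Image(L), box, boundary = "replicate"))
  m2 <- EBImage::imageData(EBImage::filter2(EBImage::Image(L * L), box, boundary = "replicate"))
  out <- pmax(0, m2 - m1 * m1)
  dim(out) <- dim(image)
  out
}

#' Fuse a z-stack into an all-in-focus composite (extended depth of field)
#'
#' For every pixel, the layer with the highest focus measure on the reference
#' channel is selected (ties go to the lowest layer index); the resulting
#' index map is median-smoothed to suppress isolated layer switches, and every
#' channel is composited by reading each pixel from its index-map layer, so
#' channels stay co-registered.
#'
#' @param stack an [ImageStack-class].
#' @param referenceChannel channel driving the index map; brightfield by
#'   default (present before any staining).
#' @param window focus-measure neighbourhood radius, pixels.
#' @param smooth median-filter radius applied to the index map, pixels; 0
#'   disables smoothing.
#' @return a [CompositeImage-class]. A single-layer stack fuses to itself with
#'   an all-zero index map.
#' @export
#' @examples
#' sc <- generateScene(3, 40, xyExtent = 256, seed = 1)
#' st <- renderStack(sc, planZStack(1100, 4), channels = "brightfield", seed = 2)
#' fuseStack(st)
fuseStack <- function(stack, referenceChannel = "brightfield", window = 4,
                      smooth = 2) {
  stopifnot(is(stack, "ImageStack"))
  ref <- match(referenceChannel, stack@channelNames)
  stopIfNot(!is.na(ref), paste0("reference channel '", referenceChannel,
                                "' not in stack (", paste(stack@channelNames, collapse = ", "), ")"))
  d <- dim(stack@pixels)
  nr <- d[1]; nc <- d[2]; nch <- d[3]; nl <- d[4]
  npx <- nr * nc

  if (nl == 1L) {
    idx <- rep(1L, npx)
  } else {
    fm <- matrix(0, npx, nl)
    for (l in seq_len(nl))
      fm[, l] <- as.vector(focusMeasure(stack@pixels[, , ref, l], window))
    idx <- max.col(fm, ties.method = "first")
    if (smooth > 0) {
      idx01 <- matrix((idx - 1) / (nl - 1), nr, nc)
      sm <- EBImage::imageData(EBImage::medianFilter(EBImage::Image(idx01), size = smooth))
      idx <- as.integer(pmin(nl, pmax(1, round(sm * (nl - 1)) + 1)))
    }
  }

  comp <- array(0, dim = c(nr, nc, nch))
  sel <- cbind(seq_len(npx), idx)
  for (c in seq_len(nch)) {
    ch <- matrix(stack@pixels[, , c, ], npx, nl)
    comp[, , c] <- matrix(ch[sel], nr, nc)
  }
  new("CompositeImage", pixels = comp,
      indexMap = matrix(as.integer(idx - 1L), nr, nc),
      pixelSize = stack@pixelSize, channelNames = stack@channelNames,
      provenance = list(reference_channel = referenceChannel, window = window,
                        smooth = smooth, n_layers = nl,
                        layer_positions = stack@layerPositions))
}
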