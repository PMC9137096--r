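## shared fixtures: small scenes and stacks built in code at test time

quietOptics <- function(...) opticalModel(noiseSd = 0, ...)

## a small stained scene in a single 512 x 512 um field
smallScene <- function(n = 6, diameter = 50, seed = 3, xy = 512) {
  applyStaining(generateScene(n, diameter, gelDepth = 1100, xyExtent = xy,
                              seed = seed),
                stainingModel(2, 60), seed = seed + 1L)
}

## analytic soft-edged disk rasteriser, written independently of the renderer:
## pixel (i, j) centre at ((j - .5), (i - .5)) * ps; linear edge ramp over 1 px
oracleDisk <- function(nr, nc, cx, cy, r, ps, amplitude = 1) {
  jj <- ((seq_len(nc)) - 0.5) * ps
  ii <- ((seq_len(nr)) - 0.5) * ps
  dist <- sqrt(outer((ii - cy)^2, (jj - cx)^2, `+`)) / ps
  m <- amplitude * pmin(1, pmax(0, r / ps - dist + 0.5))
  dim(m) <- c(nr, nc)
  m
}

## O(n^2) double-loop overlap oracle on a scene's ground truth
bruteOverlap <- function(scene) {
  ob <- sceneObjects(scene)
  n <- nrow(ob)
  if (n < 2) return(0)
  r <- ob$diameter / 2 + ob$shell_width
  hit <- logical(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if ((ob$x[i] - ob$x[j])^2 + (ob$y[i] - ob$y[j])^2 < (r[i] + r[j])^2)
      hit[i] <- hit[j] <- TRUE
  }
  100 * mean(hit)
}

## brute-force minimum width over a fine grid of orientations
bruteMinFeret <- function(x, y, nAngles = 3600) {
  th <- seq(0, pi, length.out = nAngles)
  min(vapply(th, function(a) {
    p <- x * cos(a) + y * sin(a)
    max(p) - min(p)
  }, 0))
}

## synthetic z-stack with one sharp, internally textured disk in the chosen
## layer and blurred copies elsewhere (texture keeps the focus measure
## informative across the whole footprint, as organoid interiors are)
sharpInLayer <- function(nl = 4, sharpLayer = 2, nr = 96, nc = 96,
                         cx = 96, cy = 96, r = 30, ps = 2, channels = "brightfield") {
  sharp <- oracleDisk(nr, nc, cx, cy, r, ps)
  tex <- 0.7 + 0.3 * sin(outer(seq_len(nr), seq_len(nc), function(i, j) i + 2 * j))
  sharp <- sharp * tex
  pix <- array(0, dim = c(nr, nc, length(channels), nl))
  for (l in seq_len(nl)) {
    img <- if (l == sharpLayer) sharp
    else pmax(EBImage::imageData(EBImage::gblur(EBImage::Image(sharp),
                                                sigma = 2 * abs(l - sharpLayer))), 0)
    for (c in seq_along(channels)) pix[, , c, l] <- img
  }
  new("ImageStack", pixels = pix, pixelSize = ps,
      layerPositions = seq_len(nl) * 100, channelNames = channels)
}
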