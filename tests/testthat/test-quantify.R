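## build a CompositeImage directly from channel matrices
makeComposite <- function(..., ps = 1) {
  chans <- list(...)
  pix <- array(0, c(dim(chans[[1]]), length(chans)))
  for (i in seq_along(chans)) pix[, , i] <- chans[[i]]
  new("CompositeImage", pixels = pix,
      indexMap = matrix(0L, dim(chans[[1]])[1], dim(chans[[1]])[2]),
      pixelSize = ps, channelNames = names(chans),
      provenance = list(n_layers = 1L))
}

test_that("segmentation of a blank image yields no objects, not an error", {
  comp <- makeComposite(brightfield = matrix(0, 64, 64))
  seg <- segmentObjects(comp)
  expect_identical(nrow(seg$records), 0L)
  expect_true(all(seg$labels == 0L))
})

test_that("a rendered disk is measured to its analytic area and short diameter", {
  disk <- oracleDisk(128, 128, 64, 64, 25, 1)
  comp <- makeComposite(brightfield = disk)
  seg <- segmentObjects(comp, minArea = 100)
  expect_identical(nrow(seg$records), 1L)
  r <- seg$records
  expect_lt(abs(r$area_um2 - pi * 25^2) / (pi * 25^2), 0.03)
  expect_lt(abs(r$short_diameter_um - 50) / 50, 0.05)
  expect_equal(r$x_um, 64, tolerance = 1)
  expect_equal(r$y_um, 64, tolerance = 1)
  ## short diameter never exceeds the equivalent-circle diameter by much
  expect_lte(r$short_diameter_um, 2 * sqrt(r$area_um2 / pi) * 1.1)
})

test_that("watershed splits a touching pair into two objects", {
  ## centres 0.8 x the sum of radii apart: footprints overlap but two cores
  d <- 0.8 * 50
  a <- oracleDisk(160, 160, 80 - d / 2, 80, 25, 1)
  b <- oracleDisk(160, 160, 80 + d / 2, 80, 25, 1)
  comp <- makeComposite(brightfield = pmin(a + b, 1))
  seg <- segmentObjects(comp, minArea = 100)
  expect_identical(nrow(seg$records), 2L)
})

test_that("minimum Feret diameter matches a brute-force rotation search", {
  set.seed(123)
  for (i in 1:5) {
    ## random blob: union of a few disks
    pts <- data.frame(x = runif(3, 20, 60), y = runif(3, 20, 60),
                      r = runif(3, 5, 15))
    img <- matrix(0, 80, 80)
    for (k in 1:3) img <- pmax(img, oracleDisk(80, 80, pts$x[k], pts$y[k], pts$r[k], 1))
    dim(img) <- c(80, 80)
    on <- which(img > 0.5, arr.ind = TRUE)
    got <- OrganoidStack:::.minFeret(on[, 2], on[, 1])
    want <- bruteMinFeret(on[, 2], on[, 1])
    expect_equal(got, want, tolerance = 0.02)
  }
})

test_that("labeling rate counts objects above the green threshold", {
  rec <- data.frame(id = 1:4, x_um = 0, y_um = 0, area_um2 = 500,
                    short_diameter_um = 25,
                    mean_green = c(0, 0, 0.5, 0.9), mean_red = 0,
                    live = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(labelingRate(rec, greenThreshold = 0.05), 50)
  expect_equal(labelingRate(transform(rec, mean_green = 0)), 0)
  expect_error(labelingRate(emptyRecords()), "empty well")
})

test_that("ground-truth overlap rate equals the O(n^2) brute force exactly", {
  expect_equal(overlapRate(generateScene(1, 100, seed = 1)), 0)

  ## two objects forced to intersect in xy -> both overlap
  ob <- data.frame(id = 1:2, x = c(100, 140), y = c(100, 100), z = c(0, 900),
                   diameter = 60, live_fraction = 1, labeled = FALSE,
                   green_intensity = 0, red_intensity = 0, shell_width = 0)
  sc2 <- new("Scene", objects = ob, gelDepth = 1100, xyExtent = c(300, 300),
             density = 2, seed = NA_integer_)
  expect_equal(overlapRate(sc2), 100)

  for (seed in 1:4) {
    sc <- generateScene(200, c(20, 60, 100), xyExtent = 2000, seed = seed)
    expect_identical(overlapRate(sc), bruteOverlap(sc))
  }
})

test_that("expected overlap increases with planting density", {
  ## 100 um spheres in a 10 uL dome at 2 -> 20 objects/uL
  side <- sqrt(10 * 1e9 / 1100)
  rates <- vapply(c(2, 8, 14, 20) * 10, function(n) {
    mean(vapply(1:3, function(s)
      overlapRate(generateScene(n, 100, xyExtent = side, seed = 100 * n + s)), 0))
  }, 0)
  expect_true(all(diff(rates) > 0))
})

test_that("detected-mode overlap is the count deficit and needs ground truth", {
  rec <- emptyRecords()[0, ]
  expect_error(overlapRate(rec, mode = "detected"), "nTrue")
  rec5 <- do.call(rbind, replicate(5, data.frame(
    id = 1L, x_um = 0, y_um = 0, area_um2 = 500, short_diameter_um = 25,
    mean_green = 0, mean_red = 0, live = FALSE), simplify = FALSE))
  expect_equal(overlapRate(rec5, mode = "detected", nTrue = 10), 50)
  expect_equal(overlapRate(rec5, mode = "detected", nTrue = 4), 0)  # clipped
  expect_error(overlapRate(generateScene(3, seed = 1), mode = "detected"), "detected")
})

test_that("background intensity recovers a constant field from nine points", {
  expect_equal(backgroundIntensity(matrix(0, 100, 100), seed = 1), 0)
  expect_equal(backgroundIntensity(matrix(0.37, 100, 100), seed = 1), 0.37)

  ## noisy constant background: error shrinks as sqrt(9 x 25) patch pixels
  set.seed(5)
  img <- matrix(0.3 + rnorm(200 * 200, 0, 0.02), 200, 200)
  est <- backgroundIntensity(img, seed = 6)
  expect_lt(abs(est - 0.3), 3 * 0.02 / sqrt(9 * 25) + 0.002)

  full <- matrix(1L, 50, 50)
  expect_error(backgroundIntensity(matrix(0, 50, 50), exclusionMask = full),
               "mask covers")
})

test_that("background sampling avoids segmented objects", {
  disk <- oracleDisk(128, 128, 64, 64, 30, 1)
  img <- disk + 0.1                     # objects at 1.1, background 0.1
  dim(img) <- c(128, 128)
  comp <- makeComposite(brightfield = img)
  seg <- segmentObjects(comp, minArea = 50)
  ## a sliver of the anti-aliased rim can leak into patches near the object,
  ## so the estimate is close to the true background, far from the object level
  est <- backgroundIntensity(img, exclusionMask = seg$labels, seed = 7)
  expect_equal(est, 0.1, tolerance = 0.05)
})

test_that("size distribution bins short diameters and conserves the count", {
  expect_true(all(sizeDistribution(emptyRecords(), c(0, 20, 100)) == 0L))

  rec <- data.frame(id = 1:7, x_um = 0, y_um = 0, area_um2 = 1,
                    short_diameter_um = c(5, 25, 30, 50, 99, 150, 150),
                    mean_green = 0, mean_red = 0, live = FALSE)
  h <- sizeDistribution(rec, c(0, 20, 100, 200))
  expect_identical(sum(h), 7L)
  expect_identical(as.integer(h), c(1L, 4L, 2L))

  same <- data.frame(id = 1:5, x_um = 0, y_um = 0, area_um2 = 1,
                     short_diameter_um = 50, mean_green = 0, mean_red = 0,
                     live = FALSE)
  h2 <- sizeDistribution(same, c(0, 20, 100, 200))
  expect_identical(as.integer(h2), c(0L, 5L, 0L))
})
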