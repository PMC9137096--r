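test_that("generateScene places the requested objects inside the volume, reproducibly", {
  empty <- generateScene(0, seed = 1)
  expect_s4_class(empty, "Scene")
  expect_identical(nrow(sceneObjects(empty)), 0L)

  sc <- generateScene(100, diameter = 20, gelDepth = 1100,
                      xyExtent = c(2000, 2000), seed = 42)
  ob <- sceneObjects(sc)
  expect_identical(nrow(ob), 100L)
  expect_true(all(ob$z >= 0 & ob$z <= 1100))
  expect_true(all(ob$x >= 10 & ob$x <= 1990))
  expect_true(all(ob$diameter == 20))
  expect_true(all(ob$live_fraction == 1))
  expect_false(any(ob$labeled))

  again <- generateScene(100, diameter = 20, gelDepth = 1100,
                         xyExtent = c(2000, 2000), seed = 42)
  expect_identical(sceneObjects(again), ob)

  other <- generateScene(100, diameter = 20, gelDepth = 1100,
                         xyExtent = c(2000, 2000), seed = 43)
  expect_false(identical(sceneObjects(other)$x, ob$x))
})

test_that("scene density reflects count over volume", {
  ## 10 uL equivalent volume at 1100 um depth, 200 objects -> 20/uL
  side <- sqrt(10 * 1e9 / 1100)
  sc <- generateScene(200, 20, gelDepth = 1100, xyExtent = side, seed = 7)
  expect_equal(sceneDensity(sc), 20, tolerance = 1e-9)
})

test_that("generateScene rejects invalid parameters", {
  expect_error(generateScene(-1, seed = 1), "nObjects")
  expect_error(generateScene(10, gelDepth = 0, seed = 1), "gelDepth")
  expect_error(generateScene(10, diameter = -5, seed = 1), "positive")
  expect_error(generateScene(10, xyExtent = c(100, -1), seed = 1), "xyExtent")
})

test_that("staining labels live objects with probability min(1, c*t/K)", {
  sc <- generateScene(200, 30, seed = 5)

  none <- applyStaining(sc, stainingModel(concentration = 0, time = 60), seed = 6)
  expect_false(any(sceneObjects(none)$labeled))
  expect_true(all(sceneObjects(none)$green_intensity == 0))

  ## saturating condition: 2 uM x 60 min / K=120 -> p = 1
  full <- applyStaining(sc, stainingModel(2, 60), seed = 6)
  expect_true(all(sceneObjects(full)$labeled))
  expect_equal(labelingRate(full), 100)

  ## p = 0.5 at n = 1000: labeled fraction within 3 binomial SE of 0.5
  big <- generateScene(1000, 30, xyExtent = 6000, seed = 8)
  half <- applyStaining(big, stainingModel(1, 60), seed = 9)
  frac <- mean(sceneObjects(half)$labeled)
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 1000))
})

test_that("labeled fraction is monotone in concentration and time", {
  sc <- generateScene(800, 30, xyExtent = 5000, seed = 11)
  fracAt <- function(c, t)
    mean(sceneObjects(applyStaining(sc, stainingModel(c, t), seed = 12))$labeled)
  byC <- vapply(c(0.25, 0.5, 1, 2), fracAt, 0, t = 30)
  byT <- vapply(c(15, 30, 60, 120), function(t) fracAt(1, t), 0)
  expect_true(all(diff(byC) >= 0))
  expect_true(all(diff(byT) >= 0))
})

test_that("treatment kills the stated fraction and reshapes survivors", {
  sc <- applyStaining(generateScene(100, 60, xyExtent = 3000, seed = 20),
                      stainingModel(2, 60), seed = 21)

  same <- applyTreatment(sc, treatmentEffect(0, 1, 0), seed = 22)
  expect_identical(sceneObjects(same), sceneObjects(sc))

  dead <- applyTreatment(sc, treatmentEffect(1, 1, 0), seed = 22)
  expect_true(all(sceneObjects(dead)$live_fraction == 0))
  expect_true(all(sceneObjects(dead)$green_intensity == 0))
  expect_true(all(sceneObjects(dead)$red_intensity > 0))

  ## kill_fraction = 0.6 at n = 500: dead count within 3 binomial SE of 300
  big <- generateScene(500, 60, xyExtent = 6000, seed = 23)
  tr <- applyTreatment(big, treatmentEffect(0.6, 1, 0), seed = 24)
  nDead <- sum(sceneObjects(tr)$live_fraction == 0)
  expect_lt(abs(nDead - 300), 3 * sqrt(500 * 0.6 * 0.4))

  ## survivors: shrunken live core inside a dead shell
  shr <- applyTreatment(sc, treatmentEffect(0, 0.6, 15), seed = 25)
  ob0 <- sceneObjects(sc); ob1 <- sceneObjects(shr)
  expect_equal(ob1$diameter, ob0$diameter * 0.6)
  expect_true(all(ob1$shell_width == 15))
  ## live-core footprint never exceeds the total (core + shell) footprint
  expect_true(all(ob1$diameter / 2 <= ob1$diameter / 2 + ob1$shell_width))
})
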