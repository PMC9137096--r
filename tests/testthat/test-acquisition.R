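test_that("planZStack rounds the step and anchors planes at the gel bottom", {
  p7 <- planZStack(1100, 7)
  expect_equal(stepSize(p7), 180)           # 1100/6 = 183.3 -> nearest 10
  expect_equal(layerPositions(p7), seq(0, 1080, by = 180))

  p2 <- planZStack(1100, 2)
  expect_equal(stepSize(p2), 1100)
  expect_equal(layerPositions(p2), c(0, 1100))

  p11 <- planZStack(1100, 11)
  expect_equal(stepSize(p11), 110)          # exact division: rounding is a no-op

  p1 <- planZStack(1100, 1)
  expect_equal(layerPositions(p1), 550)
  expect_equal(stepSize(p1), 0)

  expect_error(planZStack(1100, 0), "nLayers")
  expect_error(planZStack(0, 5), "zRange")

  exact <- planZStack(1100, 7, roundTo = 0)
  expect_equal(stepSize(exact), 1100 / 6)
})

test_that("closed-form capture efficiency follows min(1, 2(r + h)/step)", {
  optics <- opticalModel()   # h = 80
  p7 <- planZStack(1100, 7)
  expect_equal(captureEfficiencyClosedForm(20, p7, optics), 1)

  wide <- new("AcquisitionPlan", zRange = 1200, nLayers = 4L, step = 400,
              layerPositions = c(0, 400, 800, 1200))
  expect_equal(captureEfficiencyClosedForm(20, wide, optics), 0.45)  # 180/400

  ## plateau: any diameter with step <= 2 (r + h) captures everything
  for (d in c(20, 60, 100))
    expect_equal(captureEfficiencyClosedForm(
      d, planZStack(2 * (d / 2 + 80), 2, roundTo = 0), optics), 1)

  ## single-layer scans refer the band to the full range
  p1 <- planZStack(1100, 1)
  expect_equal(captureEfficiencyClosedForm(20, p1, optics), 2 * 90 / 1100)
})

test_that("capture curves are monotone and consistent with the scalar form", {
  tab <- captureCurve(c(10, 20, 30, 60, 100), c(2, 4, 7, 10, 14))
  expect_true(all(c("diameter_um", "n_layers", "step_um", "frac_count",
                    "frac_area") %in% names(tab)))
  ## monotone non-decreasing in layers for every diameter, and in diameter
  for (d in unique(tab$diameter_um)) {
    sub <- tab[tab$diameter_um == d, ]
    expect_true(all(diff(sub$frac_count[order(sub$n_layers)]) >= 0))
  }
  for (n in unique(tab$n_layers)) {
    sub <- tab[tab$n_layers == n, ]
    expect_true(all(diff(sub$frac_count[order(sub$diameter_um)]) >= 0))
  }
  ## larger diameters plateau at fewer layers
  layersToPlateau <- function(d) min(tab$n_layers[tab$diameter_um == d &
                                                    tab$frac_count >= 1])
  plateaus <- vapply(unique(tab$diameter_um), layersToPlateau, 0L)
  expect_true(all(diff(plateaus) <= 0))
  expect_equal(tab$frac_count[tab$diameter_um == 100 & tab$n_layers == 7], 1)
  expect_lt(tab$frac_count[tab$diameter_um == 10 & tab$n_layers == 4], 1)

  one <- captureCurve(20, 7)
  expect_identical(nrow(one), 1L)
  expect_equal(one$frac_count, captureEfficiencyClosedForm(20, planZStack(1100, 7)))
})

test_that("Monte-Carlo capture matches the closed form within 3 binomial SE", {
  nSim <- 2000
  cf <- captureCurve(c(10, 20, 100), c(2, 4, 7), mode = "closed_form")
  mc <- captureCurve(c(10, 20, 100), c(2, 4, 7), mode = "empirical",
                     nSim = nSim, seed = 99)
  se <- sqrt(pmax(cf$frac_count * (1 - cf$frac_count), 1e-12) / nSim)
  expect_true(all(abs(mc$frac_count - cf$frac_count) <= pmax(3 * se, 0.01)))
})

test_that("full render-fuse-detect capture agrees with the closed form", {
  ## 20 um spheres, 4-layer scan: closed form well below 1, so the comparison
  ## is informative; modest n keeps the runtime down
  optics <- opticalModel()
  sc <- generateScene(300, 20, gelDepth = 1100, xyExtent = 3015, seed = 31)
  p4 <- planZStack(1100, 4)
  f <- captureEfficiencyEmpirical(sc, p4, optics, seed = 32)
  cf <- captureEfficiencyClosedForm(20, p4, optics)
  se <- sqrt(cf * (1 - cf) / 300)
  expect_lt(abs(as.numeric(f) - cf), 3 * se + 0.02)  # + small detection slack
  expect_false(attr(f, "flag_overdetection"))
})
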