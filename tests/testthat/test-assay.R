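## quick well summaries with a given count and total area
fakeWell <- function(n, areaEach = 1000) {
  if (n == 0) return(wellSummary(emptyRecords()))
  wellSummary(data.frame(id = seq_len(n), x_um = 0, y_um = 0,
                         area_um2 = areaEach, short_diameter_um = 30,
                         mean_green = 1, mean_red = 0, live = TRUE))
}

test_that("survival rate is the dN/d0 count percentage", {
  expect_equal(survivalRate(timepointPair(fakeWell(100), fakeWell(40))), 40)
  expect_equal(survivalRate(timepointPair(fakeWell(50), fakeWell(50))), 100)
  expect_equal(survivalRate(timepointPair(fakeWell(50), fakeWell(60))), 120)
  expect_error(survivalRate(timepointPair(fakeWell(0), fakeWell(5))),
               "division by zero")
})

test_that("size-change ratio is the dN/d0 area percentage", {
  expect_equal(sizeChangeRatio(timepointPair(fakeWell(10), fakeWell(10))), 100)
  expect_equal(sizeChangeRatio(timepointPair(fakeWell(10), fakeWell(0))), 0)
  expect_equal(sizeChangeRatio(timepointPair(fakeWell(10, 1000), fakeWell(10, 250))), 25)
  expect_equal(sizeChangeRatio(timepointPair(fakeWell(10), fakeWell(10)),
                               asChange = TRUE), 0)
  expect_error(sizeChangeRatio(timepointPair(fakeWell(0), fakeWell(0))), "area")
})

test_that("shrinking survivor cores scales the area ratio with the square", {
  ## ground-truth areas: shrink factor s with no kill -> ratio = 100 s^2
  sc <- generateScene(80, c(40, 80), xyExtent = 3000, seed = 7)
  s <- 0.6
  tr <- applyTreatment(sc, treatmentEffect(0, s, 0), seed = 8)
  a0 <- sum(pi * (sceneObjects(sc)$diameter / 2)^2)
  a1 <- sum(pi * (sceneObjects(tr)$diameter / 2)^2)
  expect_equal(100 * a1 / a0, 100 * s^2, tolerance = 1e-9)
})

test_that("chemosensitivity calls split at the configured cutoff", {
  expect_identical(classifyChemosensitivity(30)@call, "sensitive")
  expect_identical(classifyChemosensitivity(36.42)@call, "resistant")  # boundary
  expect_identical(classifyChemosensitivity(36.41)@call, "sensitive")
  expect_identical(classifyChemosensitivity(80)@call, "resistant")
  expect_identical(classifyChemosensitivity(50, cutoff = 60)@call, "sensitive")
  expect_error(classifyChemosensitivity(-1), "non-negative")
})

test_that("bisection of the decision rule recovers the boundary to 0.01", {
  lo <- 0; hi <- 100
  while (hi - lo > 0.005) {
    mid <- (lo + hi) / 2
    if (classifyChemosensitivity(mid)@call == "sensitive") lo <- mid else hi <- mid
  }
  expect_lt(abs((lo + hi) / 2 - 36.42), 0.01)
})

test_that("staining grid hits its anchors and is monotone", {
  g <- stainingGrid(c(0, 0.5, 1, 2), c(15, 30, 60), nOrganoids = 400, seed = 3)
  expect_true(all(g$labeling_rate_pct[g$concentration_uM == 0] == 0))
  expect_equal(g$labeling_rate_pct[g$concentration_uM == 2 & g$time_min == 60], 100)
  ## saturation: every cell with c*t >= K is exactly 100%
  sat <- g$concentration_uM * g$time_min >= 120
  expect_true(all(g$labeling_rate_pct[sat] == 100))
  ## expectation monotone along both axes
  for (t in unique(g$time_min)) {
    sub <- g[g$time_min == t, ]
    expect_true(all(diff(sub$expected_pct[order(sub$concentration_uM)]) >= 0))
  }
  for (cc in unique(g$concentration_uM)) {
    sub <- g[g$concentration_uM == cc, ]
    expect_true(all(diff(sub$expected_pct[order(sub$time_min)]) >= 0))
  }
  ## simulated rates within 3 binomial SE of the model expectation
  se <- sqrt(pmax(g$expected_pct / 100 * (1 - g$expected_pct / 100), 1e-12) / 400)
  expect_true(all(abs(g$labeling_rate_pct - g$expected_pct) <= 100 * pmax(3 * se, 1e-9)))
})

test_that("group comparison flags real effects and not identical groups", {
  same <- compareGroups(c(10, 11, 9, 10.5), list(also = c(10, 11, 9, 10.5)))
  expect_gt(same$p_value[2], 0.9)
  expect_identical(same$stars[2], "ns")

  ## doubled survival at low noise and n = 5 wells: detectable at P < 0.05
  set.seed(17)
  ctrl <- rnorm(5, 30, 2)
  eff <- compareGroups(ctrl, list(mitigator = rnorm(5, 60, 2)))
  expect_lt(eff$p_value[2], 0.05)
  expect_true(eff$mean[2] > eff$mean[1])
  expect_true(eff$stars[2] %in% c("*", "**", "***", "****"))

  expect_error(compareGroups(c(1), list(g = c(1, 2))), "wells")
  expect_error(compareGroups(c(1, 2), list(g = 3)), "wells")
})

test_that("group comparison extracts metrics from timepoint pairs", {
  mk <- function(n0, n1) timepointPair(fakeWell(n0), fakeWell(n1))
  ctrl <- list(mk(100, 95), mk(100, 98), mk(100, 97))
  drug <- list(mk(100, 40), mk(100, 45), mk(100, 38))
  tab <- compareGroups(ctrl, list(drug = drug), metric = "survival_rate")
  expect_equal(tab$mean[1], mean(c(95, 98, 97)))
  expect_equal(tab$mean[2], mean(c(40, 45, 38)))
  expect_lt(tab$p_value[2], 0.001)
})
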