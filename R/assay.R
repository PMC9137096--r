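#' Survival rate as percent of day 0
#'
#' 100 x (objects at day N) / (objects at day 0). May exceed 100 when new
#' organoids formed after treatment start.
#'
#' @param pair a [TimepointPair-class].
#' @param ... unused.
#' @return percent (>= 0).
#' @name survivalRate
#' @export
#' @examples
#' d0 <- wellSummary(data.frame(id = 1:10, x_um = 0, y_um = 0, area_um2 = 100,
#'                              short_diameter_um = 10, mean_green = 1,
#'                              mean_red = 0, live = TRUE))
#' survivalRate(timepointPair(d0, d0))  # 100
setMethod("survivalRate", "TimepointPair", function(pair, ...) {
  if (pair@d0@nObjects == 0L)
    stop("survival rate undefined: no objects at day 0 (division by zero)",
         call. = FALSE)
  100 * pair@dN@nObjects / pair@d0@nObjects
})

#' Size-change ratio as percent of day 0 area
#'
#' 100 x (total area at day N) / (total area at day 0), the chemosensitivity
#' readout. The alternative convention, percent change
#' 100 x (dN - d0) / d0, is available via `asChange = TRUE`.
#'
#' @param pair a [TimepointPair-class].
#' @param asChange report the signed percent change instead of the ratio.
#' @param ... unused.
#' @return percent.
#' @name sizeChangeRatio
#' @export
setMethod("sizeChangeRatio", "TimepointPair", function(pair, asChange = FALSE, ...) {
  if (pair@d0@totalArea <= 0)
    stop("size-change ratio undefined: day-0 total area is zero", call. = FALSE)
  ratio <- 100 * pair@dN@totalArea / pair@d0@totalArea
  if (asChange) ratio - 100 else ratio
})

#' Classify chemosensitivity from the size-change ratio
#'
#' Ratios below the cutoff are called sensitive (the treatment suppressed
#' growth); ratios at or above it resistant -- the boundary itself is assigned
#' to resistant. The default cutoff of 36.42 percent is the configured
#' decision boundary of the assay; the direction and boundary convention are
#' package conventions and both are overridable.
#'
#' @param ratio size-change ratio in percent (>= 0).
#' @param cutoff decision boundary in percent.
#' @return a [ChemoCall-class].
#' @export
#' @examples
#' classifyChemosensitivity(30)      # sensitive
#' classifyChemosensitivity(36.42)   # resistant (boundary convention)
classifyChemosensitivity <- function(ratio, cutoff = 36.42) {
  stopIfNot(is.numeric(ratio) && length(ratio) == 1L && is.finite(ratio) &&
              ratio >= 0, "ratio must be a single non-negative percent")
  call <- if (ratio < cutoff) "sensitive" else "resistant"
  new("ChemoCall", sizeChangeRatio = ratio, cutoff = cutoff, call = call)
}

#' Simulated labeling-rate grid over staining conditions
#'
#' For every (concentration, time) cell, simulates `nOrganoids` independent
#' live organoids stained under those conditions and reports the resulting
#' labeling rate. The expectation is 100 x min(1, c*t/K), non-decreasing in
#' both concentration and time.
#'
#' @param concentrations dye concentrations, uM.
#' @param times staining times, minutes.
#' @param model a [StainingModel-class] template supplying K and quencher
#'   settings.
#' @param nOrganoids organoids simulated per cell.
#' @param seed integer seed (per-cell substreams are derived from it).
#' @return data.frame with columns concentration_uM, time_min,
#'   labeling_rate_pct, expected_pct.
#' @export
#' @examples
#' stainingGrid(c(0.5, 1, 2), c(15, 30, 60), nOrganoids = 100, seed = 1)
stainingGrid <- function(concentrations, times, model = stainingModel(),
                         nOrganoids = 200, seed = NULL) {
  stopIfNot(length(concentrations) >= 1 && length(times) >= 1,
            "concentration and time grids must be non-empty")
  stopIfNot(nOrganoids >= 1, "nOrganoids must be >= 1")
  grid <- expand.grid(concentration_uM = as.numeric(concentrations),
                      time_min = as.numeric(times))
  rate <- expd <- numeric(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    sm <- stainingModel(concentration = grid$concentration_uM[i],
                        time = grid$time_min[i],
                        saturationK = model@saturationK,
                        cuConcentration = model@cuConcentration,
                        backgroundRate = model@backgroundRate,
                        quenchReference = model@quenchReference)
    p <- labelingProbability(sm)
    lab <- withSeed(if (is.null(seed)) NULL else seed + i,
                    stats::runif(nOrganoids) < p)
    rate[i] <- 100 * mean(lab)
    expd[i] <- 100 * p
  }
  grid$labeling_rate_pct <- rate
  grid$expected_pct <- expd
  grid
}

## pull a per-well metric out of whatever the caller supplied
.metricValues <- function(wells, metric) {
  if (is.numeric(wells)) return(as.numeric(wells))
  stopIfNot(is.list(wells), "each group must be a numeric vector or a list")
  vapply(wells, function(w) {
    if (is(w, "TimepointPair")) {
      switch(metric,
             survival_rate = survivalRate(w),
             total_area = w@dN@totalArea)
    } else if (is(w, "WellSummary")) {
      switch(metric,
             survival_rate = stop("survival_rate needs TimepointPair wells",
                                  call. = FALSE),
             total_area = w@totalArea)
    } else if (is.numeric(w) && length(w) == 1L) {
      as.numeric(w)
    } else stop("wells must be numeric, WellSummary or TimepointPair", call. = FALSE)
  }, 0)
}

.stars <- function(p) {
  if (p < 1e-4) "****" else if (p < 1e-3) "***" else if (p < 0.01) "**"
  else if (p < 0.05) "*" else "ns"
}

#' Compare treated groups against a control
#'
#' Per-group mean and spread of a per-well metric, plus a two-tailed Student's
#' t test of each treated group against the control, annotated with the usual
#' significance stars (* P < 0.05, ** P < 0.01, *** P < 0.001,
#' **** P < 0.0001). Pairwise tests are unadjusted, matching common practice
#' for a handful of planned treated-vs-control contrasts; no multiplicity
#' correction is applied.
#'
#' @param control control-group wells: a numeric vector of metric values or a
#'   list of [WellSummary-class] / [TimepointPair-class] objects (>= 2 wells).
#' @param treatedGroups named list of treated groups, same forms as `control`.
#' @param metric "survival_rate" or "total_area"; ignored for numeric input.
#' @param spread "sd" or "sem".
#' @return data.frame with columns group, n, mean, sd or sem, p_value (NA for
#'   the control row), stars.
#' @export
#' @examples
#' compareGroups(c(10, 12, 9), list(drug = c(25, 30, 28)))
compareGroups <- function(control, treatedGroups,
                          metric = c("survival_rate", "total_area"),
                          spread = c("sd", "sem")) {
  metric <- match.arg(metric)
  spread <- match.arg(spread)
  stopIfNot(is.list(treatedGroups) && length(treatedGroups) >= 1 &&
              !is.null(names(treatedGroups)) && all(nzchar(names(treatedGroups))),
            "treatedGroups must be a non-empty named list")
  ctrl <- .metricValues(control, metric)
  stopIfNot(length(ctrl) >= 2, "control group needs >= 2 wells (variance undefined)")
  rows <- list(data.frame(group = "control", n = length(ctrl), mean = mean(ctrl),
                          spread = if (spread == "sd") stats::sd(ctrl)
                                   else stats::sd(ctrl) / sqrt(length(ctrl)),
                          p_value = NA_real_, stars = "", stringsAsFactors = FALSE))
  for (g in names(treatedGroups)) {
    v <- .metricValues(treatedGroups[[g]], metric)
    stopIfNot(length(v) >= 2,
              paste0("group '", g, "' needs >= 2 wells (variance undefined)"))
    p <- if (stats::sd(v) == 0 && stats::sd(ctrl) == 0) {
      if (mean(v) == mean(ctrl)) 1 else 0
    } else stats::t.test(v, ctrl, alternative = "two.sided")$p.value
    rows[[g]] <- data.frame(group = g, n = length(v), mean = mean(v),
                            spread = if (spread == "sd") stats::sd(v)
                                     else stats::sd(v) / sqrt(length(v)),
                            p_value = p, stars = .stars(p),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  names(out)[names(out) == "spread"] <- spread
  rownames(out) <- NULL
  attr(out, "metric") <- metric
  out
}
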