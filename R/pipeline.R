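#' Quantify one simulated well end to end
#'
#' Convenience wrapper for the per-well imaging path: render the scene with
#' the given plan and optics, fuse the z-stack, segment the chosen channel,
#' and assemble a [WellSummary-class] (labeling rate from the records,
#' overlap rate from the ground truth, background from the green composite).
#'
#' @param scene a [Scene-class] (stain/treat it first as needed).
#' @param plan an [AcquisitionPlan-class].
#' @param optics an [OpticalModel-class].
#' @param staining a [StainingModel-class] (drives the green background).
#' @param channel channel to segment for counting.
#' @param channels channels to render.
#' @param minArea,greenThreshold segmentation settings, see [segmentObjects()].
#' @param seed integer seed for rendering noise and background sampling.
#' @return a [WellSummary-class].
#' @export
quantifyWell <- function(scene, plan, optics = opticalModel(),
                         staining = stainingModel(),
                         channel = "brightfield",
                         channels = c("brightfield", "green", "red"),
                         minArea = 314,
                         greenThreshold = defaultGreenThreshold(optics),
                         seed = NULL) {
  st <- renderStack(scene, plan, optics, channels = channels,
                    staining = staining, seed = seed)
  comp <- fuseStack(st, referenceChannel = intersect(
    c("brightfield", channels), channels)[1])
  seg <- segmentObjects(comp, channel = channel, minArea = minArea,
                        greenThreshold = greenThreshold)
  lr <- if (nrow(seg$records)) labelingRate(seg$records, greenThreshold) else NA_real_
  bg <- if ("green" %in% channels)
    backgroundIntensity(getChannel(comp, "green"), exclusionMask = seg$labels,
                        seed = seed) else NA_real_
  wellSummary(seg$records, labelingRate = lr,
              overlapRate = overlapRate(scene), backgroundMean = bg)
}

#' Run the full simulate-fuse-quantify-assay pipeline
#'
#' Simulates a small plate: for the control group and every treated group,
#' `n_wells` wells are generated, imaged at day 0 (brightfield, untreated),
#' then treated, stained, imaged again, and quantified. Survival rate
#' (live-object count, green channel) and size-change ratio are computed per
#' well; the groups are compared against control with two-tailed t tests and
#' a chemosensitivity call is made from each group's mean size-change ratio.
#'
#' Outputs written under `outDir`: per-well object CSVs, a `wells.csv`
#' summary, a `groups.csv` comparison table, the resolved configuration
#' (`config_resolved.yaml`), and `log.txt` recording every stage's parameters
#' and timing. Identical seeds reproduce every CSV byte for byte (only the
#' log carries wall-clock timings).
#'
#' @param config nested configuration list, see [defaultRunConfig()]; group
#'   entries under `assay$groups` may override `treatment` fields per group.
#' @param outDir output directory (created if needed).
#' @return invisibly, a list with `wells` (data.frame), `comparison`
#'   (data.frame), and `calls` (named list of [ChemoCall-class]).
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile("run")) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(outDir, "log.txt")
  logCon <- file(logPath, "w")
  on.exit(close(logCon))
  logMsg <- function(...) {
    writeLines(paste0(format(Sys.time(), "%H:%M:%S "), sprintf(...)), logCon)
  }
  t0 <- proc.time()[3]

  optics <- .opticsFromConfig(config$optics)
  staining <- .stainingFromConfig(config$staining)
  plan <- .planFromConfig(config$plan)
  th <- config$thresholds
  sc <- config$scene
  day <- config$assay$day
  nWells <- config$assay$n_wells
  groups <- config$assay$groups
  stopIfNot(nWells >= 1, "assay$n_wells must be >= 1")

  writeRunConfig(config, file.path(outDir, "config_resolved.yaml"))
  logMsg("resolved config written; seed=%d, %d well(s)/group, day %d",
         config$seed, nWells, day)
  logMsg("plan: %d layers over %g um (step %g um)", plan@nLayers,
         plan@zRange, plan@step)

  diamFun <- function(n) stats::runif(n, sc$diameter_min, sc$diameter_max)
  allGroups <- c(list(control = NULL), groups)
  wellRows <- list()
  pairsByGroup <- list()
  wellId <- 0L

  for (g in names(allGroups)) {
    trCfg <- mergeCfg(config$treatment, allGroups[[g]])
    effect <- if (g == "control") treatmentEffect(0, 1, 0)
              else .treatmentFromConfig(trCfg)
    pairs <- vector("list", nWells)
    for (w in seq_len(nWells)) {
      wellId <- wellId + 1L
      seedW <- config$seed + 101L * wellId
      tW0 <- proc.time()[3]
      scene0 <- generateScene(sc$n_objects, diameter = diamFun,
                              gelDepth = sc$gel_depth,
                              xyExtent = sc$xy_extent, seed = seedW)
      d0 <- quantifyWell(scene0, plan, optics, staining,
                         channel = "brightfield", channels = "brightfield",
                         minArea = th$min_area,
                         greenThreshold = th$green_threshold, seed = seedW + 1L)
      sceneN <- applyTreatment(scene0, effect, seed = seedW + 2L)
      sceneN <- applyStaining(sceneN, staining, seed = seedW + 3L)
      dN <- quantifyWell(sceneN, plan, optics, staining, channel = "green",
                         minArea = th$min_area * effect@shrinkFactor^2,
                         greenThreshold = th$green_threshold, seed = seedW + 4L)
      pair <- timepointPair(d0, dN, day = day)
      pairs[[w]] <- pair
      writeRecordsCSV(d0, file.path(outDir, sprintf("well%03d_d0.csv", wellId)))
      writeRecordsCSV(dN, file.path(outDir, sprintf("well%03d_d%d.csv", wellId, day)))
      wellRows[[wellId]] <- data.frame(
        well = wellId, group = g, seed = seedW,
        n_d0 = nObjects(d0), n_dN = nObjects(dN),
        area_d0_um2 = totalArea(d0), area_dN_um2 = totalArea(dN),
        survival_pct = survivalRate(pair),
        size_change_pct = sizeChangeRatio(pair),
        labeling_pct = dN@labelingRate, overlap_pct = d0@overlapRate,
        background = dN@backgroundMean)
      logMsg("well %03d (%s): d0 n=%d, d%d n=%d, survival %.1f%% [%.1fs]",
             wellId, g, nObjects(d0), day, nObjects(dN),
             survivalRate(pair), proc.time()[3] - tW0)
    }
    pairsByGroup[[g]] <- pairs
  }

  wells <- do.call(rbind, wellRows)
  utils::write.csv(wells, file.path(outDir, "wells.csv"), row.names = FALSE)

  treated <- pairsByGroup[setdiff(names(pairsByGroup), "control")]
  comparison <- if (length(treated))
    compareGroups(pairsByGroup$control, treated, metric = "survival_rate")
  else NULL
  if (!is.null(comparison))
    utils::write.csv(comparison, file.path(outDir, "groups.csv"), row.names = FALSE)

  calls <- lapply(pairsByGroup, function(pairs) {
    classifyChemosensitivity(mean(vapply(pairs, sizeChangeRatio, 0)),
                             cutoff = th$cutoff)
  })
  callDf <- data.frame(group = names(calls),
                       size_change_pct = vapply(calls, function(x) x@sizeChangeRatio, 0),
                       cutoff = th$cutoff,
                       call = vapply(calls, function(x) x@call, ""))
  utils::write.csv(callDf, file.path(outDir, "chemo_calls.csv"), row.names = FALSE)

  logMsg("pipeline finished in %.1fs; outputs in %s", proc.time()[3] - t0, outDir)
  invisible(list(wells = wells, comparison = comparison, calls = calls,
                 outDir = outDir))
}
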