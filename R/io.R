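## required sidecar metadata for a plain-TIFF stack
.sidecarFields <- c("pixel_size_um", "layer_positions_um", "channels")

#' Write / read an ImageStack as multi-page TIFF with a JSON sidecar
#'
#' The stack is stored as an uncompressed 16-bit multi-page TIFF, one page per
#' channel x layer in channel-major order (all layers of the first channel,
#' then the second, ...). Physical calibration travels in a JSON sidecar
#' (`<path>.json`) with fields pixel_size_um, layer_positions_um and channels.
#' Because rendered intensities live on the 16-bit grid, the round trip is
#' bit-identical.
#'
#' @param stack an [ImageStack-class].
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `writeStack` returns `path` invisibly; `readStack` returns the
#'   [ImageStack-class].
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  d <- dim(stack@pixels)
  pages <- vector("list", d[3] * d[4])
  k <- 0L
  for (c in seq_len(d[3])) for (l in seq_len(d[4])) {
    k <- k + 1L
    pages[[k]] <- stack@pixels[, , c, l]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none",
                  reduce = FALSE)
  meta <- list(pixel_size_um = stack@pixelSize,
               layer_positions_um = stack@layerPositions,
               channels = stack@channelNames,
               page_order = "channel-major")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeStack
#' @param sidecar path of the JSON sidecar; defaults to `<path>.json`.
#' @export
readStack <- function(path, sidecar = paste0(path, ".json")) {
  stopIfNot(file.exists(path), paste("no such TIFF:", path))
  if (!file.exists(sidecar))
    stop("missing calibration sidecar '", sidecar, "'; a plain TIFF stack ",
         "needs a JSON sidecar with fields: ",
         paste(.sidecarFields, collapse = ", "), call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  missing <- setdiff(.sidecarFields, names(meta))
  if (length(missing))
    stop("sidecar '", sidecar, "' lacks required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nch <- length(meta$channels)
  nl <- length(meta$layer_positions_um)
  stopIfNot(length(pages) == nch * nl,
            "page count does not match channels x layers in the sidecar")
  d1 <- dim(pages[[1]])
  pix <- array(0, dim = c(d1[1], d1[2], nch, nl))
  k <- 0L
  for (c in seq_len(nch)) for (l in seq_len(nl)) {
    k <- k + 1L
    pix[, , c, l] <- pages[[k]]
  }
  new("ImageStack", pixels = pix, pixelSize = as.numeric(meta$pixel_size_um),
      layerPositions = as.numeric(meta$layer_positions_um),
      channelNames = as.character(meta$channels))
}

#' Write / read a scene ground-truth table as CSV
#'
#' One row per object (id, x, y, z, diameter, live_fraction, labeled,
#' green_intensity, red_intensity, shell_width); the gel geometry and seed are
#' kept in `#`-prefixed header comments so the scene round-trips from the one
#' file.
#'
#' @param scene a [Scene-class].
#' @param path CSV path.
#' @return `writeSceneCSV` returns `path` invisibly; `readSceneCSV` the
#'   reconstructed [Scene-class].
#' @export
writeSceneCSV <- function(scene, path) {
  stopifnot(is(scene, "Scene"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# gel_depth_um=%.10g", scene@gelDepth),
    sprintf("# xy_extent_um=%.10g,%.10g", scene@xyExtent[1], scene@xyExtent[2]),
    sprintf("# seed=%s", ifelse(is.na(scene@seed), "NA", scene@seed))
  ), con)
  utils::write.csv(scene@objects, con, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSceneCSV
#' @export
readSceneCSV <- function(path) {
  stopIfNot(file.exists(path), paste("no such file:", path))
  hdr <- readLines(path, n = 3L)
  stopIfNot(all(startsWith(hdr, "#")),
            "not a scene CSV: expected 3 '#' header lines with gel geometry")
  getv <- function(key) sub(paste0("# ", key, "="), "", hdr[grepl(key, hdr)], fixed = TRUE)
  gel <- as.numeric(getv("gel_depth_um"))
  xy <- as.numeric(strsplit(getv("xy_extent_um"), ",")[[1]])
  seed <- suppressWarnings(as.integer(getv("seed")))
  ob <- utils::read.csv(path, comment.char = "#")
  ob$labeled <- as.logical(ob$labeled)
  volume_uL <- xy[1] * xy[2] * gel / 1e9
  new("Scene", objects = ob, gelDepth = gel, xyExtent = xy,
      density = nrow(ob) / volume_uL,
      seed = if (length(seed) && !is.na(seed)) seed else NA_integer_)
}

#' Write per-object records or a well summary as CSV
#'
#' @param x data.frame of records or a [WellSummary-class].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeRecordsCSV <- function(x, path) {
  if (is(x, "WellSummary")) x <- x@records
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a pipeline run configuration (YAML)
#'
#' A run configuration is a plain named list with blocks `scene`, `optics`,
#' `staining`, `treatment`, `plan`, `thresholds`, `assay`, plus a top-level
#' `seed`. [defaultRunConfig()] documents every field; unknown fields are
#' preserved, so configurations round-trip losslessly.
#'
#' @param path YAML file path.
#' @param config named list (e.g. from [defaultRunConfig()]).
#' @return `readRunConfig` returns the config list merged over the defaults;
#'   `writeRunConfig` returns `path` invisibly.
#' @export
readRunConfig <- function(path) {
  stopIfNot(file.exists(path), paste("no such config:", path))
  user <- yaml::read_yaml(path)
  mergeCfg(defaultRunConfig(), user)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

## recursive right-biased merge of config lists
mergeCfg <- function(base, over) {
  if (is.null(over)) return(base)
  if (!is.list(over)) return(over)
  for (k in names(over)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(over[[k]]))
      mergeCfg(base[[k]], over[[k]]) else over[[k]]
  }
  base
}

#' Default pipeline configuration
#'
#' The demo assay design: 48-well-plate-style wells of 50 organoids in a
#' 10 uL, 1100 um-deep gel dome, scanned with 7 layers, stained at the
#' saturating condition (2 uM, 60 min) with the 0.1 mM Cu2+ quencher, and a
#' treatment killing half of the objects with survivor cores shrunk to 60
#' percent inside a 10 um dead shell.
#'
#' @return nested named list; see the fields themselves for units.
#' @export
defaultRunConfig <- function() {
  list(
    seed = 1L,
    scene = list(n_objects = 50L, diameter_min = 40, diameter_max = 100,
                 gel_depth = 1100, xy_extent = 3015),
    optics = list(pixel_size = 2, blur_coeff = 0.05, dof_half_depth = 80,
                  noise_sd = 0.01, background_base = 0.02),
    staining = list(concentration = 2, time = 60, saturation_k = 120,
                    cu_concentration = 0.1, background_rate = 0.002,
                    quench_reference = 0.1),
    treatment = list(kill_fraction = 0.5, shrink_factor = 0.6,
                     dead_shell_width = 10),
    plan = list(z_range = 1100, n_layers = 7L, round_to = 10),
    thresholds = list(min_area = 314, green_threshold = 0.05, cutoff = 36.42),
    assay = list(n_wells = 3L, day = 10L, groups = list(treated = NULL))
  )
}

## constructors from config blocks
.opticsFromConfig <- function(cfg) opticalModel(
  pixelSize = cfg$pixel_size, blurCoeff = cfg$blur_coeff,
  dofHalfDepth = cfg$dof_half_depth, noiseSd = cfg$noise_sd,
  backgroundBase = cfg$background_base)

.stainingFromConfig <- function(cfg) stainingModel(
  concentration = cfg$concentration, time = cfg$time,
  saturationK = cfg$saturation_k, cuConcentration = cfg$cu_concentration,
  backgroundRate = cfg$background_rate, quenchReference = cfg$quench_reference)

.treatmentFromConfig <- function(cfg) treatmentEffect(
  killFraction = cfg$kill_fraction, shrinkFactor = cfg$shrink_factor,
  deadShellWidth = cfg$dead_shell_width)

.planFromConfig <- function(cfg) planZStack(
  zRange = cfg$z_range, nLayers = cfg$n_layers, roundTo = cfg$round_to)
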