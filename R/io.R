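#' Read a sequence of scan frames from image files
#'
#' Files are read in the given order, checked for equal width, and
#' returned as [ScanFrame-class] objects with 0-based contiguous indices.
#' 16-bit PNG input is rescaled to the 8-bit range with a warning.
#'
#' @param paths character vector of PNG/TIFF file paths, in frame order.
#' @param taskId task identifier stamped on each frame.
#' @return list of [ScanFrame-class].
#' @export
readFrames <- function(paths, taskId = "task") {
  stopIfNot(length(paths) >= 1, "need at least one frame file")
  frames <- vector("list", length(paths))
  for (i in seq_along(paths)) {
    p <- paths[i]
    if (!file.exists(p)) stop(sprintf("input error: no such file: %s", p),
                              call. = FALSE)
    if (grepl("\\.png$", p, ignore.case = TRUE)) {
      hdr <- readBin(p, "raw", n = 25)
      if (length(hdr) == 25 && as.integer(hdr[25]) == 16)
        warning(sprintf("%s: 16-bit input rescaled to 8-bit", p))
    }
    img <- tryCatch(EBImage::readImage(p), error = function(e)
      stop(sprintf("input error: cannot read %s: %s", p, conditionMessage(e)),
           call. = FALSE))
    d <- EBImage::imageData(img)
    if (length(dim(d)) == 2L) d <- array(rep(d, 3), c(dim(d), 3L))
    if (dim(d)[3] > 3L) d <- d[, , 1:3, drop = FALSE]
    # EBImage stores x (image columns) first; our rasters are rows x cols
    px <- aperm(d, c(2L, 1L, 3L))
    px <- round(px * 255)
    frames[[i]] <- ScanFrame(px, frameIndex = i - 1L, taskId = taskId)
  }
  widths <- vapply(frames, function(f) dim(f@pixels)[2], integer(1))
  if (length(unique(widths)) != 1L)
    stop("input error: frames differ in width", call. = FALSE)
  frames
}

#' Write scan frames as numbered PNG files
#'
#' @param frames list of [ScanFrame-class] (or one raster array).
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
writeFrames <- function(frames, dir, prefix = "frame") {
  if (is(frames, "ScanFrame") || is.array(frames)) frames <- list(frames)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(frames))
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    px <- if (is(f, "ScanFrame")) f@pixels else f
    img <- EBImage::Image(aperm(px / 255, c(2L, 1L, 3L)),
                          colormode = "Color")
    paths[i] <- file.path(dir, sprintf("%s-%03d.png", prefix, i - 1L))
    EBImage::writeImage(img, paths[i])
  }
  invisible(paths)
}

#' Score one task: frames in, per-leaf and per-plant traits out
#'
#' The full scoring pipeline: per-frame channel re-registration,
#' stitching, 8-bit HSL conversion, band segmentation (total mask = green
#' + yellow), seam bridging, impurity removal, 8-connected leaf
#' extraction, per-leaf morphometrics and aggregation into the 29
#' per-plant traits.
#'
#' Seam bridging: per-frame correction leaves `max(offsets)` rows of
#' background fill at the bottom of every frame, which would cut any leaf
#' crossing that frame boundary. A scan-axis-only morphological closing
#' (height `2*max(offsets)+1`, width 1) on the stitched total mask
#' bridges those seams without merging side-by-side leaves.
#'
#' @param frames list of [ScanFrame-class] (raw, mis-registered input).
#' @param profile a [CalibrationProfile-class].
#' @param bands a [BandSet-class].
#' @param minAreaPx impurity threshold, pixels (see [removeImpurities()]).
#' @param minLeafPx minimum leaf size, pixels (see [extractLeaves()]).
#' @param correct apply [correctChannels()] to each frame first.
#' @param seamBridge bridge frame-boundary seams (ignored when all
#'   offsets are zero).
#' @param taskId identifier; defaults to the frames' task id.
#' @return list with `leaves` (per-leaf data.frame), `plant`
#'   ([PlantTraits-class], or `NULL` with a warning when no leaf is
#'   found) and `log` (per-stage counts).
#' @export
scoreTask <- function(frames, profile = defaultCalibration(),
                      bands = defaultBands(), minAreaPx = 50,
                      minLeafPx = 200, correct = TRUE, seamBridge = TRUE,
                      taskId = NULL) {
  stopIfNot(length(frames) >= 1, "need at least one frame")
  if (is.null(taskId)) taskId <- frames[[1]]@taskId
  off <- channelOffsets(profile)
  if (correct)
    frames <- lapply(frames, correctChannels, offsets = off)
  canvas <- stitchFrames(frames)
  hsl <- rgbToHsl8(canvas)
  total <- totalLeafMask(hsl, bands)
  maxOff <- max(off)
  if (seamBridge && maxOff > 0L && length(frames) > 1L) {
    kern <- matrix(1, 2L * maxOff + 1L, 1L)
    total <- EBImage::imageData(
      EBImage::closing(EBImage::Image(total * 1), kern)) > 0.5
  }
  nBefore <- if (any(total)) max(label8(total)) else 0L
  total <- removeImpurities(total, minAreaPx)
  nAfter <- if (any(total)) max(label8(total)) else 0L
  cm <- classMasks(total, hsl, bands)
  leaves <- extractLeaves(total, cm, minLeafPx)
  log <- list(frames = length(frames),
              components = nBefore,
              impuritiesRemoved = nBefore - nAfter,
              leaves = length(leaves))
  if (length(leaves) == 0L) {
    warning(sprintf("task '%s': no leaves found", taskId))
    return(list(leaves = data.frame(), plant = NULL, log = log))
  }
  records <- measureLeaves(leaves, profile, taskId)
  list(leaves = records,
       plant = aggregateTraits(records, plantId = taskId),
       log = log)
}

#' Render, degrade and score a synthetic task
#'
#' Convenience wrapper used throughout validation: renders the task,
#' applies channel distortion (the inverse of the correction the pipeline
#' performs), cuts the raster into frames of the profile's height, and
#' scores the frames.
#'
#' @param task a [SyntheticTask-class].
#' @param profile a [CalibrationProfile-class].
#' @param distort simulate tri-linear mis-registration before scoring.
#' @param ... passed to [scoreTask()].
#' @return As [scoreTask()], plus `truth` (the task's analytic per-leaf
#'   truth).
#' @export
scoreSynthetic <- function(task, profile = defaultCalibration(),
                           distort = TRUE, ...) {
  scan <- renderScan(task, profile)
  raster <- scan$rgb
  if (distort)
    raster <- distortChannels(raster, channelOffsets(profile))
  frames <- splitFrames(raster, frameHeight(profile), taskId = task@plantId)
  res <- scoreTask(frames, profile, correct = distort, ...)
  res$truth <- taskTruth(task)
  res
}

#' Read / write the declarative pipeline configuration
#'
#' A single YAML file carrying the calibration (pixel pitch, magnification,
#' channel offsets, frame geometry), the five HSL bands and the size
#' thresholds. [defaultConfig()] returns the shipped defaults as a list.
#'
#' @param path YAML file path.
#' @return `readConfig()` returns a list with elements `profile`
#'   ([CalibrationProfile-class]), `bands` ([BandSet-class]), `minAreaPx`
#'   and `minLeafPx`.
#' @export
readConfig <- function(path) {
  stopIfNot(file.exists(path), sprintf("config error: no such file: %s", path))
  cfg <- yaml::read_yaml(path)
  parseBand <- function(b, nm) Band(nm, unlist(b$h), unlist(b$s), unlist(b$l))
  cal <- cfg$calibration
  profile <- CalibrationProfile(
    pixelPitch = cal$pixel_pitch_um,
    magnification = cal$magnification,
    channelOffsets = c(green = as.integer(cal$channel_offset_green),
                       blue = as.integer(cal$channel_offset_blue)),
    frameHeight = cal$frame_height_px,
    frameWidth = cal$frame_width_px)
  bands <- BandSet(
    green = parseBand(cfg$bands$green, "green"),
    yellow = parseBand(cfg$bands$yellow, "yellow"),
    green2 = parseBand(cfg$bands$green2, "green2"),
    green3 = parseBand(cfg$bands$green3, "green3"),
    green4 = parseBand(cfg$bands$green4, "green4"))
  list(profile = profile, bands = bands,
       minAreaPx = cfg$thresholds$min_area_px,
       minLeafPx = cfg$thresholds$min_leaf_px)
}

#' @rdname readConfig
#' @param profile,bands,minAreaPx,minLeafPx components to serialise.
#' @export
writeConfig <- function(path, profile = defaultCalibration(),
                        bands = defaultBands(), minAreaPx = 50,
                        minLeafPx = 200) {
  asList <- function(b) list(h = as.list(b@h), s = as.list(b@s),
                             l = as.list(b@l))
  cfg <- list(
    calibration = list(
      pixel_pitch_um = profile@pixelPitch,
      magnification = profile@magnification,
      channel_offset_green = unname(profile@channelOffsets[["green"]]),
      channel_offset_blue = unname(profile@channelOffsets[["blue"]]),
      frame_height_px = profile@frameHeight,
      frame_width_px = profile@frameWidth),
    bands = list(green = asList(bands@green), yellow = asList(bands@yellow),
                 green2 = asList(bands@green2), green3 = asList(bands@green3),
                 green4 = asList(bands@green4)),
    thresholds = list(min_area_px = minAreaPx, min_leaf_px = minLeafPx))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname readConfig
#' @export
defaultConfig <- function() {
  list(profile = defaultCalibration(), bands = defaultBands(),
       minAreaPx = 50, minLeafPx = 200)
}
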