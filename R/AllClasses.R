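#' @import methods
#' @importFrom stats rpois runif sd filter
#' @importFrom utils head tail read.csv write.csv read.delim
NULL

#' Calibration profile of the inspection unit
#'
#' Optical and geometric calibration of the line-scan inspection unit:
#' camera pixel pitch, optical magnification, the row offsets of the green
#' and blue sensor lines relative to the red line, and the frame geometry
#' used when cutting the continuous scan into images.
#'
#' The linear resolution (mm per pixel) and the area of one pixel (mm^2)
#' are derived quantities, kept unrounded internally and available through
#' [mmPerPixel()] and [areaPerPixel()].
#'
#' @slot pixelPitch numeric(1). Sensor pixel pitch in micrometres (square
#'   pixels).
#' @slot magnification numeric(1). Object-to-sensor scale factor.
#' @slot channelOffsets integer(2), named `green` and `blue`. Row shifts of
#'   the green and blue sensor lines relative to red, in scan-direction
#'   pixels (non-negative).
#' @slot frameHeight integer(1). Rows per acquired frame.
#' @slot frameWidth integer(1). Columns (transverse pixels) per frame.
#'
#' @seealso [CalibrationProfile()], [defaultCalibration()]
#' @name CalibrationProfile-class
#' @rdname CalibrationProfile-class
#' @exportClass CalibrationProfile
setClass("CalibrationProfile",
  representation(
    pixelPitch = "numeric",
    magnification = "numeric",
    channelOffsets = "integer",
    frameHeight = "integer",
    frameWidth = "integer"
  ),
  prototype(
    pixelPitch = 14,
    magnification = 15.71,
    channelOffsets = c(green = 2L, blue = 4L),
    frameHeight = 3000L,
    frameWidth = 1280L
  )
)

setValidity("CalibrationProfile", function(object) {
  msg <- character()
  if (length(object@pixelPitch) != 1L || !is.finite(object@pixelPitch) ||
      object@pixelPitch <= 0)
    msg <- c(msg, "pixelPitch must be a single positive number (um)")
  if (length(object@magnification) != 1L || !is.finite(object@magnification) ||
      object@magnification <= 0)
    msg <- c(msg, "magnification must be a single positive number")
  off <- object@channelOffsets
  if (length(off) != 2L || is.null(names(off)) ||
      !setequal(names(off), c("green", "blue")))
    msg <- c(msg, "channelOffsets must be an integer vector named 'green', 'blue'")
  else if (any(off < 0L))
    msg <- c(msg, "channelOffsets must be non-negative")
  if (length(object@frameHeight) != 1L || object@frameHeight <= 0L)
    msg <- c(msg, "frameHeight must be a positive integer")
  else if (length(off) == 2L && object@frameHeight <= max(off))
    msg <- c(msg, "frameHeight must exceed the largest channel offset")
  if (length(object@frameWidth) != 1L || object@frameWidth <= 0L)
    msg <- c(msg, "frameWidth must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' One HSL threshold band
#'
#' An inclusive axis-aligned box in 8-bit HSL space. A pixel belongs to the
#' band when its hue, saturation and lightness all lie inside the
#' respective `[min, max]` ranges (each on the 0-255 scale).
#'
#' @slot name character(1) band label.
#' @slot h,s,l integer(2) inclusive `[min, max]` ranges, 0-255.
#'
#' @seealso [Band()], [BandSet-class]
#' @name Band-class
#' @rdname Band-class
#' @exportClass Band
setClass("Band",
  representation(name = "character", h = "integer", s = "integer",
                 l = "integer"))

setValidity("Band", function(object) {
  msg <- character()
  for (ch in c("h", "s", "l")) {
    v <- slot(object, ch)
    if (length(v) != 2L || anyNA(v))
      msg <- c(msg, sprintf("%s must be integer(2)", ch))
    else if (v[1] < 0L || v[2] > 255L || v[1] > v[2])
      msg <- c(msg, sprintf("%s range must satisfy 0 <= min <= max <= 255", ch))
  }
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty string")
  if (length(msg)) msg else TRUE
})

#' Named set of segmentation bands
#'
#' The five HSL bands the scoring pipeline uses: `green` and `yellow`
#' delimit the total leaf foreground (total leaf area = green + yellow),
#' and `green2`, `green3`, `green4` split the green band into the light,
#' moderate and dark classes of the IRRI leaf colour chart. The class
#' bands must be pairwise disjoint and contained in the green band.
#'
#' @slot green,yellow,green2,green3,green4 [Band-class] objects.
#'
#' @seealso [defaultBands()]
#' @name BandSet-class
#' @rdname BandSet-class
#' @exportClass BandSet
setClass("BandSet",
  representation(green = "Band", yellow = "Band", green2 = "Band",
                 green3 = "Band", green4 = "Band"))

.bandInside <- function(inner, outer) {
  all(inner@h >= outer@h[1] & inner@h <= outer@h[2]) &&
    all(inner@s >= outer@s[1] & inner@s <= outer@s[2]) &&
    all(inner@l >= outer@l[1] & inner@l <= outer@l[2])
}

.bandsDisjoint <- function(a, b) {
  sep <- function(x, y) x[2] < y[1] || y[2] < x[1]
  sep(a@h, b@h) || sep(a@s, b@s) || sep(a@l, b@l)
}

setValidity("BandSet", function(object) {
  msg <- character()
  cls <- list(green2 = object@green2, green3 = object@green3,
              green4 = object@green4)
  for (nm in names(cls))
    if (!.bandInside(cls[[nm]], object@green))
      msg <- c(msg, sprintf("%s must be contained in the green band", nm))
  pairs <- combn(names(cls), 2)
  for (k in seq_len(ncol(pairs))) {
    a <- pairs[1, k]; b <- pairs[2, k]
    if (!.bandsDisjoint(cls[[a]], cls[[b]]))
      msg <- c(msg, sprintf("%s and %s must be disjoint", a, b))
  }
  if (length(msg)) msg else TRUE
})

#' One frame of a line-scan sequence
#'
#' A strip of the continuous scan: an 8-bit RGB raster (rows x cols x 3)
#' plus its ordinal position in the task and the plant/task identifier.
#' Rows run along the scan (time) axis; columns are transverse.
#'
#' @slot pixels numeric array `rows x cols x 3`, values 0-255.
#' @slot frameIndex integer(1), 0-based ordinal within the task.
#' @slot taskId character(1) plant/task identifier.
#'
#' @seealso [ScanFrame()], [splitFrames()], [stitchFrames()]
#' @name ScanFrame-class
#' @rdname ScanFrame-class
#' @exportClass ScanFrame
setClass("ScanFrame",
  representation(pixels = "array", frameIndex = "integer",
                 taskId = "character"))

setValidity("ScanFrame", function(object) {
  msg <- character()
  d <- dim(object@pixels)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "pixels must be a rows x cols x 3 array")
  else if (d[1] < 1L || d[2] < 1L)
    msg <- c(msg, "frame must have positive height and width")
  else {
    rng <- range(object@pixels)
    if (!all(is.finite(rng)) || rng[1] < 0 || rng[2] > 255)
      msg <- c(msg, "channel values must lie in 0-255")
  }
  if (length(object@frameIndex) != 1L || object@frameIndex < 0L)
    msg <- c(msg, "frameIndex must be a single non-negative integer")
  if (length(object@taskId) != 1L)
    msg <- c(msg, "taskId must be a single string")
  if (length(msg)) msg else TRUE
})

#' A synthetic scan task with analytic ground truth
#'
#' One simulated plant: the parametric description of its leaves (shape,
#' size, curvature, colour class, HSL centre, anchor on the canvas), the
#' canvas geometry, the dust model, the seed used for all randomness, and
#' a per-leaf ground-truth table computed analytically from the leaf
#' parameters (not from any rendering).
#'
#' @slot plantId character(1).
#' @slot leaves data.frame, one row per leaf (see [samplePlant()]).
#' @slot canvasDim integer(2) rows, cols of the rendering canvas.
#' @slot dustDensity numeric(1) expected dust specks per megapixel.
#' @slot seed integer(1).
#' @slot truth data.frame of analytic per-leaf truth (lengths and widths in
#'   mm, areas in mm^2).
#'
#' @seealso [samplePlant()], [renderScan()]
#' @name SyntheticTask-class
#' @rdname SyntheticTask-class
#' @exportClass SyntheticTask
setClass("SyntheticTask",
  representation(plantId = "character", leaves = "data.frame",
                 canvasDim = "integer", dustDensity = "numeric",
                 seed = "integer", truth = "data.frame"))

setValidity("SyntheticTask", function(object) {
  msg <- character()
  if (nrow(object@leaves) != nrow(object@truth))
    msg <- c(msg, "leaves and truth must have one row per leaf")
  if (length(object@canvasDim) != 2L || any(object@canvasDim < 1L))
    msg <- c(msg, "canvasDim must be two positive integers (rows, cols)")
  if (object@dustDensity < 0)
    msg <- c(msg, "dustDensity must be non-negative")
  if (length(msg)) msg else TRUE
})

#' The 29 per-plant leaf traits
#'
#' Named container for the per-plant trait vector produced by
#' [aggregateTraits()]: 6 size traits, 7 colour traits and 16 shape traits
#' (29 in total). Lengths are mm, areas mm^2, perimeter-to-area ratios
#' 1/mm; ratios and compactness are dimensionless.
#'
#' @slot plantId character(1).
#' @slot values named numeric(29), ordered size, colour, shape (see
#'   [traitNames()]).
#'
#' @seealso [aggregateTraits()], [traitNames()], [traitGroups()]
#' @name PlantTraits-class
#' @rdname PlantTraits-class
#' @exportClass PlantTraits
setClass("PlantTraits",
  representation(plantId = "character", values = "numeric"))

setValidity("PlantTraits", function(object) {
  nms <- traitNames()
  if (length(object@values) != length(nms) ||
      !identical(names(object@values), nms))
    return(sprintf("values must be the %d named traits in canonical order",
                   length(nms)))
  TRUE
})
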