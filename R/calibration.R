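#' Construct a calibration profile
#'
#' @param pixelPitch sensor pixel pitch in micrometres.
#' @param magnification object-to-sensor scale factor.
#' @param channelOffsets integer vector named `green`, `blue`: row shifts
#'   of the green and blue sensor lines relative to red (pixels along the
#'   scan axis).
#' @param frameHeight,frameWidth frame geometry in pixels.
#' @return A [CalibrationProfile-class] object.
#' @examples
#' prof <- CalibrationProfile(14, 15.71)
#' mmPerPixel(prof)
#' @export
CalibrationProfile <- function(pixelPitch = 14, magnification = 15.71,
                               channelOffsets = c(green = 2L, blue = 4L),
                               frameHeight = 3000L, frameWidth = 1280L) {
  off <- as.integer(channelOffsets)
  names(off) <- names(channelOffsets)
  new("CalibrationProfile", pixelPitch = as.numeric(pixelPitch),
      magnification = as.numeric(magnification), channelOffsets = off,
      frameHeight = as.integer(frameHeight),
      frameWidth = as.integer(frameWidth))
}

#' Default calibration of the inspection unit
#'
#' The stock profile: 14 um pixel pitch, magnification 15.71 (0.22 mm/px,
#' 0.048 mm^2/px), 1280 x 3000 px frames. The tri-linear row offsets are
#' free parameters of the simulation model (the physical line spacing is
#' not published); the defaults are green +2, blue +4 rows.
#'
#' @return A [CalibrationProfile-class].
#' @export
defaultCalibration <- function() CalibrationProfile()

#' @rdname CalibrationProfile-class
#' @param object,x a `CalibrationProfile`.
#' @export
setGeneric("mmPerPixel", function(x) standardGeneric("mmPerPixel"))

#' @describeIn CalibrationProfile-class unrounded linear resolution,
#'   mm per pixel.
#' @export
setMethod("mmPerPixel", "CalibrationProfile", function(x)
  x@pixelPitch / 1000 * x@magnification)

#' Area of one pixel / squared resolution
#'
#' For a numeric linear resolution (mm/px) returns its square rounded to
#' `digits` decimals (the printed precision of area resolution); for a
#' [CalibrationProfile-class] returns the unrounded pixel area used in all
#' internal area conversions.
#'
#' @param x linear resolution in mm/px, or a `CalibrationProfile`.
#' @param ... passed on (`digits` for the numeric method).
#' @return Pixel area in mm^2.
#' @examples
#' areaPerPixel(0.22)                    # 0.048
#' areaPerPixel(defaultCalibration())    # unrounded
#' @export
setGeneric("areaPerPixel", function(x, ...) standardGeneric("areaPerPixel"))

#' @rdname areaPerPixel
#' @param digits decimals to round to (default 3); `NULL` for unrounded.
#' @export
setMethod("areaPerPixel", "numeric", function(x, digits = 3) {
  stopIfNot(length(x) >= 1 && all(is.finite(x)) && all(x > 0),
            "linear resolution must be positive")
  out <- x^2
  if (!is.null(digits)) out <- round(out, digits)
  out
})

#' @rdname areaPerPixel
#' @export
setMethod("areaPerPixel", "CalibrationProfile", function(x)
  mmPerPixel(x)^2)

#' @describeIn CalibrationProfile-class green/blue row offsets.
#' @export
setGeneric("channelOffsets", function(x) standardGeneric("channelOffsets"))

#' @rdname CalibrationProfile-class
#' @export
setMethod("channelOffsets", "CalibrationProfile", function(x)
  x@channelOffsets)

#' @describeIn CalibrationProfile-class frame height in rows.
#' @export
setGeneric("frameHeight", function(x) standardGeneric("frameHeight"))

#' @rdname CalibrationProfile-class
#' @export
setMethod("frameHeight", "CalibrationProfile", function(x) x@frameHeight)

setMethod("show", "CalibrationProfile", function(object) {
  cat("CalibrationProfile\n")
  cat(sprintf("  pixel pitch     : %g um\n", object@pixelPitch))
  cat(sprintf("  magnification   : %g\n", object@magnification))
  cat(sprintf("  resolution      : %.2f mm/px (%.3f mm^2/px)\n",
              mmPerPixel(object), areaPerPixel(object)))
  cat(sprintf("  channel offsets : green %d, blue %d rows\n",
              object@channelOffsets[["green"]],
              object@channelOffsets[["blue"]]))
  cat(sprintf("  frame           : %d x %d px (cols x rows)\n",
              object@frameWidth, object@frameHeight))
})

#' Linear resolution of the inspection unit
#'
#' mm imaged per pixel: `pixelPitch/1000 * magnification`. Reported at the
#' instrument's printed precision by default (2 decimals); pass
#' `digits = NULL` for the unrounded value.
#'
#' @param pixelPitch pixel pitch in micrometres.
#' @param magnification optical magnification.
#' @param digits decimals to round to; `NULL` for unrounded.
#' @return Linear resolution in mm per pixel.
#' @examples
#' linearResolution(14, 15.71)   # 0.22
#' @export
linearResolution <- function(pixelPitch, magnification, digits = 2) {
  stopIfNot(all(is.finite(pixelPitch)) && all(pixelPitch > 0),
            "pixelPitch must be positive")
  stopIfNot(all(is.finite(magnification)) && all(magnification > 0),
            "magnification must be positive")
  out <- pixelPitch / 1000 * magnification
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Field of view of the line-scan camera
#'
#' Object-side extent imaged by a sensor dimension:
#' `sensorExtent * magnification` (2 decimals by default).
#'
#' @param sensorExtent sensor extent in mm.
#' @param magnification optical magnification.
#' @param digits decimals to round to; `NULL` for unrounded.
#' @return Field of view in mm.
#' @examples
#' fieldOfView(17.94, 15.71)   # 281.84 (transverse)
#' fieldOfView(0.24, 15.71)    # 3.77 (scan direction)
#' @export
fieldOfView <- function(sensorExtent, magnification, digits = 2) {
  stopIfNot(all(is.finite(sensorExtent)) && all(sensorExtent > 0),
            "sensorExtent must be positive")
  stopIfNot(all(is.finite(magnification)) && all(magnification > 0),
            "magnification must be positive")
  out <- sensorExtent * magnification
  if (!is.null(digits)) out <- round(out, digits)
  out
}

#' Minimum feeding-cylinder centre-line spacing
#'
#' Lower bound on the spacing between the two cylinders flanking the scan
#' line so the cylinder bodies stay outside the camera's scan-direction
#' field of view: `cylinderDiameter + scanFov`.
#'
#' @param cylinderDiameter cylinder diameter in mm.
#' @param scanFov scan-direction field of view in mm.
#' @return Minimum centre-line spacing in mm.
#' @examples
#' minCylinderSpacing(30, 3.77)   # 33.77
#' @export
minCylinderSpacing <- function(cylinderDiameter, scanFov) {
  stopIfNot(all(is.finite(cylinderDiameter)) && all(cylinderDiameter > 0),
            "cylinderDiameter must be positive")
  stopIfNot(all(is.finite(scanFov)) && all(scanFov > 0),
            "scanFov must be positive")
  cylinderDiameter + scanFov
}

#' Convert a pixel count to an area
#'
#' Leaf areas are the foreground pixel count times the pixel area of the
#' calibration profile.
#'
#' @param pixelCount non-negative pixel count (vectorised).
#' @param profile a [CalibrationProfile-class], or directly the pixel area
#'   in mm^2/px.
#' @return Area in mm^2.
#' @examples
#' pixelsToArea(1000, 0.048)              # 48
#' pixelsToArea(1000, defaultCalibration())
#' @export
pixelsToArea <- function(pixelCount, profile) {
  stopIfNot(all(is.finite(pixelCount)) && all(pixelCount >= 0),
            "pixelCount must be non-negative")
  app <- if (is.numeric(profile)) profile else areaPerPixel(profile)
  stopIfNot(all(app > 0), "pixel area must be positive")
  pixelCount * app
}
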