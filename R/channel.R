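#' Construct a scan frame
#'
#' @param pixels numeric array `rows x cols x 3`, 8-bit RGB.
#' @param frameIndex 0-based ordinal of the frame within its task.
#' @param taskId plant/task identifier.
#' @return A [ScanFrame-class].
#' @export
ScanFrame <- function(pixels, frameIndex = 0L, taskId = "task") {
  new("ScanFrame", pixels = pixels, frameIndex = as.integer(frameIndex),
      taskId = as.character(taskId))
}

setMethod("show", "ScanFrame", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ScanFrame '%s' #%d: %d x %d px RGB\n", object@taskId,
              object@frameIndex, d[1], d[2]))
})

#' @describeIn ScanFrame-class the pixel array of a frame.
#' @export
setGeneric("framePixels", function(x) standardGeneric("framePixels"))

#' @rdname ScanFrame-class
#' @param x a `ScanFrame`.
#' @export
setMethod("framePixels", "ScanFrame", function(x) x@pixels)

# shift one colour plane along the scan axis; vacated rows get `fill`
.shiftPlane <- function(plane, dr, fill) {
  h <- nrow(plane)
  if (dr == 0L) return(plane)
  out <- matrix(fill, h, ncol(plane))
  if (dr > 0L) out[(dr + 1L):h, ] <- plane[seq_len(h - dr), ]
  else out[seq_len(h + dr), ] <- plane[(1L - dr):h, ]
  out
}

#' Re-register the colour planes of a frame
#'
#' The tri-linear sensor records the red, green and blue lines at slightly
#' different scan positions, so the raw colour image is mis-registered.
#' Correction shifts the green and blue planes *up* the scan axis by their
#' line offsets, back into register with red (the reference plane, never
#' modified). Rows vacated at the bottom of the frame are filled with
#' `fill`; correction is strictly per frame (no borrowing of rows from the
#' adjoining frame), and the resulting edge-fill rows are dealt with
#' downstream by segmentation and seam bridging.
#'
#' @param frame a [ScanFrame-class] or a raw `rows x cols x 3` array.
#' @param offsets integer vector named `green`, `blue`: row offsets, each
#'   in `[0, height)`.
#' @param fill length-2 fill values for the vacated green and blue rows.
#'   The default (green 0, blue 255) pushes any colour that mixes with
#'   the fill towards blue/magenta hues, which lie outside every
#'   segmentation band, so edge-fill rows can never masquerade as leaf.
#' @return Same type as `frame`, dimensions unchanged.
#' @examples
#' prof <- defaultCalibration()
#' fr <- ScanFrame(array(0, c(8, 4, 3)))
#' correctChannels(fr, channelOffsets(prof))
#' @export
correctChannels <- function(frame, offsets, fill = c(green = 0, blue = 255)) {
  isFrame <- is(frame, "ScanFrame")
  px <- if (isFrame) frame@pixels else frame
  h <- dim(px)[1]
  g <- as.integer(offsets[["green"]]); b <- as.integer(offsets[["blue"]])
  stopIfNot(g >= 0L && b >= 0L && g < h && b < h,
            "offsets must lie in [0, frame height)")
  fill <- rep_len(fill, 2L)
  px[, , 2] <- .shiftPlane(px[, , 2], -g, fill[1])
  px[, , 3] <- .shiftPlane(px[, , 3], -b, fill[2])
  if (isFrame) ScanFrame(px, frame@frameIndex, frame@taskId) else px
}

#' Simulate tri-linear channel mis-registration
#'
#' The inverse of [correctChannels()]: displaces the green and blue planes
#' *down* the scan axis by their offsets, padding the vacated top rows
#' with `fill`. Applying [correctChannels()] afterwards restores the
#' original raster on all rows except the bottom `max(offsets)` ones.
#'
#' @param raster numeric array `rows x cols x 3` (or [ScanFrame-class]).
#' @param offsets integer vector named `green`, `blue`.
#' @param fill length-2 pad values for the vacated green and blue rows.
#' @return Same type as `raster`.
#' @export
distortChannels <- function(raster, offsets, fill = c(green = 0, blue = 255)) {
  isFrame <- is(raster, "ScanFrame")
  px <- if (isFrame) raster@pixels else raster
  h <- dim(px)[1]
  g <- as.integer(offsets[["green"]]); b <- as.integer(offsets[["blue"]])
  stopIfNot(g >= 0L && b >= 0L && g < h && b < h,
            "offsets must lie in [0, raster height)")
  fill <- rep_len(fill, 2L)
  px[, , 2] <- .shiftPlane(px[, , 2], g, fill[1])
  px[, , 3] <- .shiftPlane(px[, , 3], b, fill[2])
  if (isFrame) ScanFrame(px, raster@frameIndex, raster@taskId) else px
}
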