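#' Stitch adjoining frames back into the task canvas
#'
#' Frames are concatenated along the scan axis in `frameIndex` order.
#' Leaves that were cut at a frame boundary become whole again when
#' components are labelled globally on the stitched canvas, which is
#' equivalent to cutting the partial leaf from the previous image and
#' reconnecting it to its remainder in the next.
#'
#' @param frames list of [ScanFrame-class] sharing width and task id, with
#'   contiguous indices.
#' @return numeric array `rows x cols x 3` (the stitched canvas).
#' @export
stitchFrames <- function(frames) {
  stopIfNot(length(frames) >= 1, "need at least one frame")
  idx <- vapply(frames, function(f) f@frameIndex, integer(1))
  frames <- frames[order(idx)]
  idx <- sort(idx)
  stopIfNot(identical(idx, seq(idx[1], by = 1L, length.out = length(idx))),
            "frame indices must be contiguous")
  widths <- vapply(frames, function(f) dim(f@pixels)[2], integer(1))
  stopIfNot(length(unique(widths)) == 1L, "frames must share width")
  ids <- unique(vapply(frames, function(f) f@taskId, character(1)))
  stopIfNot(length(ids) == 1L, "frames must share task id")
  rows <- sum(vapply(frames, function(f) dim(f@pixels)[1], integer(1)))
  out <- array(0, c(rows, widths[1], 3))
  at <- 1L
  for (f in frames) {
    h <- dim(f@pixels)[1]
    out[at:(at + h - 1L), , ] <- f@pixels
    at <- at + h
  }
  out
}

#' Extract whole-leaf objects from canvas masks
#'
#' Labels the impurity-cleaned total mask with 8-connectivity, keeps
#' components of at least `minLeafPx` pixels, and intersects each with the
#' class masks. Objects are ordered by bounding-box top row, then left
#' column.
#'
#' @param totalMask impurity-cleaned logical canvas mask.
#' @param classMaskList named list of logical masks (`green2`, `green3`,
#'   `green4`, `yellow`) as returned by [classMasks()].
#' @param minLeafPx minimum leaf size in pixels (default 200, about
#'   9.7 mm^2: separates the smallest rice leaf from surviving
#'   impurities).
#' @return list of leaf objects; each has `mask` (logical matrix cropped
#'   to the bounding box), `bbox` (row0, col0, row1, col1; half-open),
#'   `pixelCount` and `classPixelCounts`.
#' @export
extractLeaves <- function(totalMask, classMaskList = NULL, minLeafPx = 200) {
  lab <- label8(totalMask)
  if (max(lab) == 0L) return(list())
  sizes <- tabulate(lab)
  keep <- which(sizes >= minLeafPx)
  if (length(keep) == 0L) return(list())
  pix <- which(lab > 0L, arr.ind = TRUE)
  lpix <- lab[pix]
  out <- vector("list", length(keep))
  for (j in seq_along(keep)) {
    k <- keep[j]
    pts <- pix[lpix == k, , drop = FALSE]
    r0 <- min(pts[, 1]); r1 <- max(pts[, 1])
    c0 <- min(pts[, 2]); c1 <- max(pts[, 2])
    mask <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    mask[cbind(pts[, 1] - r0 + 1L, pts[, 2] - c0 + 1L)] <- TRUE
    counts <- integer(0)
    if (!is.null(classMaskList))
      counts <- vapply(classMaskList, function(cm) sum(cm[pts]), numeric(1))
    out[[j]] <- list(mask = mask,
                     bbox = c(row0 = r0, col0 = c0, row1 = r1 + 1L,
                              col1 = c1 + 1L),
                     pixelCount = nrow(pts),
                     classPixelCounts = counts)
  }
  ord <- order(vapply(out, function(o) o$bbox[["row0"]], numeric(1)),
               vapply(out, function(o) o$bbox[["col0"]], numeric(1)))
  out[ord]
}
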