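#' @name synthetic-scanner
#' @title Synthetic line-scan generator
#' @description
#' The generator renders plants of parametric leaves into a long scan
#' raster with exact, analytically known ground truth, then degrades the
#' raster the way the instrument would: tri-linear channel
#' mis-registration ([distortChannels()]), dust specks, and cutting into
#' fixed-height frames ([splitFrames()]). It exists so that every pipeline
#' stage can be validated against truth that does not depend on the
#' pipeline itself.
#'
#' Three blade shapes are supported. `rectangle` is the straight-blade
#' limit; `tapered-ellipse` narrows towards both tips; `curved-blade`
#' sweeps a constant-width blade along a circular arc (curvature 0-1 maps
#' to an arc angle of 0-90 degrees). Lengths and widths are snapped to
#' whole pixels of the calibration profile so rectangle truth is exact
#' under rasterisation.
NULL

.classCodes <- c(green2 = 2L, green3 = 3L, green4 = 4L, yellow = 5L)

# sample an HSL centre strictly inside a band (margin keeps every noised
# pixel far enough from the band edge that 8-bit RGB round-tripping can
# never move it outside: noise +-3 plus quantisation stays < margin)
.sampleCentre <- function(band, margin = 11L) {
  pick <- function(rng) {
    lo <- rng[1] + margin; hi <- rng[2] - margin
    if (lo > hi) stop("band too narrow for the sampling margin")
    sample(lo:hi, 1L)
  }
  c(h = pick(band@h), s = pick(band@s), l = pick(band@l))
}

# analytic geometry of one leaf, in pixel units
.leafGeometry <- function(shape, lenPx, widPx, curvature) {
  if (shape == "curved-blade") {
    theta <- max(curvature, 0.05) * pi / 2
    R <- lenPx / theta
    hw <- widPx / 2
    bboxH <- 2 * (R + hw) * sin(theta / 2)
    bboxW <- (R + hw) - (R - hw) * cos(theta / 2)
    list(theta = theta, R = R,
         bbox = c(ceiling(bboxH) + 2L, ceiling(bboxW) + 2L),
         areaPx = theta * R * widPx,
         perimPx = 2 * theta * R + 2 * widPx)
  } else if (shape == "tapered-ellipse") {
    a <- lenPx / 2; b <- widPx / 2
    list(bbox = c(lenPx, widPx),
         areaPx = pi * a * b,
         perimPx = pi * (3 * (a + b) - sqrt((3 * a + b) * (a + 3 * b))))
  } else {
    list(bbox = c(lenPx, widPx),
         areaPx = lenPx * widPx,
         perimPx = 2 * (lenPx + widPx))
  }
}

# rasterise one leaf into a logical bbox matrix (pixel-centre test)
.rasterLeaf <- function(shape, lenPx, widPx, curvature) {
  geo <- .leafGeometry(shape, lenPx, widPx, curvature)
  h <- geo$bbox[1]; w <- geo$bbox[2]
  if (shape == "rectangle") return(matrix(TRUE, h, w))
  x <- matrix(seq_len(h) - 0.5, h, w)        # row coordinate
  y <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
  if (shape == "tapered-ellipse") {
    a <- lenPx / 2; b <- widPx / 2
    ((x - a) / a)^2 + ((y - b) / b)^2 <= 1
  } else {
    hw <- widPx / 2
    Cr <- h / 2
    Cc <- -(geo$R - hw) * cos(geo$theta / 2) + 1
    dx <- x - Cr; dy <- y - Cc
    rho <- sqrt(dx^2 + dy^2)
    phi <- atan2(dx, dy)
    abs(phi) <= geo$theta / 2 & rho >= geo$R - hw & rho <= geo$R + hw
  }
}

#' Sample a synthetic plant
#'
#' Draws `nLeaves` leaves (colour class from `classMix`, shape, size and
#' curvature uniform in their ranges, dimensions snapped to whole pixels),
#' packs them left-to-right in shelves on a canvas as wide as one frame,
#' and computes the analytic per-leaf ground truth. Leaves never overlap
#' by construction; when the canvas is taller than one frame the packing
#' is nudged so that at least one leaf spans a frame boundary.
#'
#' @param nLeaves number of leaves (>= 1).
#' @param classMix named proportions over `green2`, `green3`, `green4`,
#'   `yellow`; must sum to 1. Default is a green-dominated plant.
#' @param seed integer seed; the task is fully determined by it.
#' @param profile a [CalibrationProfile-class].
#' @param lengthRange,widthRange leaf length / maximum width ranges in mm.
#' @param shapes candidate blade shapes.
#' @param curvatureRange curvature range for `curved-blade` (0 = straight,
#'   1 = quarter circle).
#' @param dustDensity expected dust specks per megapixel of canvas.
#' @param plantId task identifier.
#' @param margin clearance between leaves and canvas borders, pixels.
#' @return A [SyntheticTask-class].
#' @examples
#' task <- samplePlant(5, seed = 1, lengthRange = c(30, 60),
#'                     widthRange = c(6, 10))
#' task
#' @export
samplePlant <- function(nLeaves,
                        classMix = c(green2 = 0.3, green3 = 0.4,
                                     green4 = 0.2, yellow = 0.1),
                        seed = 1L,
                        profile = defaultCalibration(),
                        lengthRange = c(120, 280),
                        widthRange = c(8, 14),
                        shapes = c("rectangle", "tapered-ellipse",
                                   "curved-blade"),
                        curvatureRange = c(0.2, 0.9),
                        dustDensity = 5,
                        plantId = sprintf("plant-%d", seed),
                        margin = 12L) {
  stopIfNot(nLeaves >= 1, "nLeaves must be >= 1")
  stopIfNot(abs(sum(classMix) - 1) < 1e-8, "classMix must sum to 1")
  stopIfNot(all(names(classMix) %in% names(.classCodes)),
            "classMix names must be green2/green3/green4/yellow")
  bands <- defaultBands()
  mmpp <- mmPerPixel(profile)
  cols <- profile@frameWidth
  withSeed(seed, {
    cls <- sample(names(classMix), nLeaves, replace = TRUE, prob = classMix)
    shp <- sample(shapes, nLeaves, replace = TRUE)
    lenPx <- round(runif(nLeaves, lengthRange[1], lengthRange[2]) / mmpp)
    widPx <- round(runif(nLeaves, widthRange[1], widthRange[2]) / mmpp)
    widPx <- pmin(widPx, lenPx - 1L)  # length > width always
    curv <- runif(nLeaves, curvatureRange[1], curvatureRange[2])
    curv[shp != "curved-blade"] <- 0
    centres <- t(vapply(cls, function(k) .sampleCentre(getBand(bands, k)),
                        numeric(3)))
    # shelf packing
    geo <- lapply(seq_len(nLeaves), function(i)
      .leafGeometry(shp[i], lenPx[i], widPx[i], curv[i]))
    bboxH <- vapply(geo, function(g) as.integer(g$bbox[1]), integer(1))
    bboxW <- vapply(geo, function(g) as.integer(g$bbox[2]), integer(1))
    if (any(bboxW + 2L * margin > cols))
      stop("canvas too small: a leaf is wider than the frame", call. = FALSE)
    row0 <- col0 <- integer(nLeaves)
    rb <- margin + 1L; cc <- margin + 1L; bandH <- 0L
    for (i in seq_len(nLeaves)) {
      if (cc + bboxW[i] + margin - 1L > cols) {
        rb <- rb + bandH + margin; cc <- margin + 1L; bandH <- 0L
      }
      row0[i] <- rb; col0[i] <- cc
      cc <- cc + bboxW[i] + margin
      bandH <- max(bandH, bboxH[i])
    }
    rows <- rb + bandH + margin
    # make sure some leaf straddles a frame boundary when there is one
    fh <- profile@frameHeight
    if (rows > fh) {
      crosses <- any(row0 %/% fh != (row0 + bboxH - 1L) %/% fh)
      if (!crosses) {
        mid <- row0 + bboxH %/% 2L
        i <- which.min(abs(mid - fh))
        delta <- fh - mid[i]
        if (delta > 0L) { row0 <- row0 + delta; rows <- rows + delta }
      }
    }
    leaves <- data.frame(
      leaf = seq_len(nLeaves), shape = shp, class = cls,
      length_px = lenPx, width_px = widPx, curvature = curv,
      h = centres[, 1], s = centres[, 2], l = centres[, 3],
      row0 = row0, col0 = col0, bbox_h = bboxH, bbox_w = bboxW,
      stringsAsFactors = FALSE)
    app <- areaPerPixel(profile)
    areaMm <- vapply(geo, function(g) g$areaPx, numeric(1)) * app
    truth <- data.frame(
      leaf = seq_len(nLeaves), class = cls, shape = shp,
      length_mm = lenPx * mmpp, width_mm = widPx * mmpp,
      area_mm2 = areaMm,
      perimeter_mm = vapply(geo, function(g) g$perimPx, numeric(1)) * mmpp,
      stringsAsFactors = FALSE)
    for (k in names(.classCodes))
      truth[[paste0("area_", k)]] <- ifelse(cls == k, areaMm, 0)
    new("SyntheticTask", plantId = plantId, leaves = leaves,
        canvasDim = c(as.integer(rows), as.integer(cols)),
        dustDensity = as.numeric(dustDensity), seed = as.integer(seed),
        truth = truth)
  })
}

setMethod("show", "SyntheticTask", function(object) {
  cat(sprintf("SyntheticTask '%s': %d leaves on %d x %d px canvas, seed %d\n",
              object@plantId, nrow(object@leaves), object@canvasDim[1],
              object@canvasDim[2], object@seed))
  print(table(object@leaves$class))
})

#' @describeIn samplePlant analytic per-leaf ground truth of a task.
#' @param task a [SyntheticTask-class].
#' @export
taskTruth <- function(task) task@truth

# one random-walk dust speck; returns n x 2 pixel coords or NULL
.sampleSpeck <- function(size, rows, cols) {
  r <- sample(2:(rows - 1L), 1L); c <- sample(2:(cols - 1L), 1L)
  pts <- matrix(c(r, c), 1, 2)
  while (nrow(pts) < size) {
    step <- pts[nrow(pts), ] + sample(c(-1L, 0L, 1L), 2L, replace = TRUE)
    if (step[1] < 2L || step[1] > rows - 1L || step[2] < 2L ||
        step[2] > cols - 1L) break
    pts <- rbind(pts, step)
  }
  unique(pts)
}

#' Render a synthetic task to a clean scan raster
#'
#' Paints every leaf with per-pixel HSL jitter around its band centre
#' (jitter is clipped so no pixel can leave its class band, even after
#' 8-bit RGB quantisation), adds dust specks of 1-20 pixels in random
#' colours (half of them drawn inside leaf colour bands, placed on
#' background only, clear of leaves), and returns the truth label rasters
#' alongside the image. Rendering is deterministic given the task.
#'
#' @param task a [SyntheticTask-class].
#' @param profile the [CalibrationProfile-class] used when sampling.
#' @param background background RGB (default light grey: achromatic, so it
#'   falls outside every band).
#' @param noise half-width of the uniform per-pixel HSL jitter.
#' @return list with `rgb` (rows x cols x 3 array), `labels` (integer
#'   matrix, 0 = background, k = leaf k) and `classes` (integer matrix,
#'   0 = background, 2/3/4 = green class, 5 = yellow).
#' @export
renderScan <- function(task, profile = defaultCalibration(),
                       background = c(235, 235, 235), noise = 3L) {
  rows <- task@canvasDim[1]; cols <- task@canvasDim[2]
  rgb <- array(0, c(rows, cols, 3))
  rgb[, , 1] <- background[1]; rgb[, , 2] <- background[2]
  rgb[, , 3] <- background[3]
  labels <- matrix(0L, rows, cols)
  classes <- matrix(0L, rows, cols)
  lv <- task@leaves
  bands <- defaultBands()
  withSeed(task@seed + 1L, {
    for (i in seq_len(nrow(lv))) {
      m <- .rasterLeaf(lv$shape[i], lv$length_px[i], lv$width_px[i],
                       lv$curvature[i])
      n <- sum(m)
      if (n == 0L) next
      band <- getBand(bands, lv$class[i])
      jit <- function(centre, rng) {
        v <- centre + sample((-noise):noise, n, replace = TRUE)
        pmin(pmax(v, rng[1] + 8L), rng[2] - 8L)
      }
      px <- hsl8ToRgb(jit(lv$h[i], band@h), jit(lv$s[i], band@s),
                      jit(lv$l[i], band@l))
      rs <- lv$row0[i] + seq_len(nrow(m)) - 1L
      cs <- lv$col0[i] + seq_len(ncol(m)) - 1L
      sel <- which(m)
      for (ch in 1:3) {
        plane <- rgb[rs, cs, ch]
        plane[sel] <- px[, ch]
        rgb[rs, cs, ch] <- plane
      }
      labels[rs, cs][sel] <- i
      classes[rs, cs][sel] <- .classCodes[[lv$class[i]]]
    }
    nSpecks <- rpois(1, task@dustDensity * rows * cols / 1e6)
    for (k in seq_len(nSpecks)) {
      pts <- .sampleSpeck(sample(1:20, 1L), rows, cols)
      if (is.null(pts) || nrow(pts) == 0L) next
      # keep specks clear of leaves (and their 1-px halo)
      halo <- rbind(pts,
                    sweep(pts, 2, c(1L, 0L), "+"), sweep(pts, 2, c(-1L, 0L), "+"),
                    sweep(pts, 2, c(0L, 1L), "+"), sweep(pts, 2, c(0L, -1L), "+"))
      if (any(labels[halo] != 0L)) next
      col <- if (runif(1) < 0.5) {
        sample(0:255, 3, replace = TRUE)
      } else {
        band <- getBand(bands, sample(names(.classCodes), 1L))
        ctr <- .sampleCentre(band)
        as.vector(hsl8ToRgb(ctr[1], ctr[2], ctr[3]))
      }
      for (ch in 1:3) {
        plane <- rgb[, , ch]
        plane[pts] <- col[ch]
        rgb[, , ch] <- plane
      }
    }
  })
  list(rgb = rgb, labels = labels, classes = classes)
}

#' Cut a scan raster into fixed-height frames
#'
#' Concatenating the returned frames in order reproduces the raster
#' exactly; the last frame may be shorter.
#'
#' @param raster numeric array `rows x cols x 3`.
#' @param frameHeight rows per frame (> 0).
#' @param taskId identifier stamped on each frame.
#' @return list of [ScanFrame-class], ordered by `frameIndex`.
#' @export
splitFrames <- function(raster, frameHeight, taskId = "task") {
  stopIfNot(frameHeight >= 1, "frameHeight must be positive")
  rows <- dim(raster)[1]
  starts <- seq(1L, rows, by = as.integer(frameHeight))
  lapply(seq_along(starts), function(i) {
    r0 <- starts[i]
    r1 <- min(r0 + frameHeight - 1L, rows)
    ScanFrame(raster[r0:r1, , , drop = FALSE], frameIndex = i - 1L,
              taskId = taskId)
  })
}
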