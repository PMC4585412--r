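#' @name morphometrics
#' @title Per-leaf morphometrics
#' @description
#' Rice blades curl, so axis-aligned bounding boxes misstate their
#' dimensions. Leaf length is therefore measured along the morphological
#' skeleton: the longest geodesic between skeleton endpoints, extended at
#' each end by the local inscribed radius (the distance-transform value)
#' so the measurement reaches the blade tips. Leaf width is twice the
#' maximum inscribed radius along the skeleton, minus half a pixel to
#' undo the pixel-centre offset of the distance transform. The perimeter
#' is the length of the closed polygon through the traced contour pixel
#' centres after a light (window-3) circular moving-average smoothing,
#' which removes the staircase bias of raw chain codes on curved
#' outlines. Compactness is the isoperimetric quotient `4*pi*A/P^2`.
NULL

# pad a mask with a 1-px background border so the distance transform sees
# background even for components that fill their bounding box
.padMask <- function(mask) {
  out <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  out[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  out
}

# length of a pixel path after window-(2k+1) moving-average smoothing;
# removes the staircase bias of 8-connected chains on oblique runs
.smoothPathLength <- function(coords, k = 2L) {
  n <- nrow(coords)
  if (n < 2L) return(0)
  if (n > 2L * k + 1L && k > 0L) {
    sm <- apply(coords, 2, function(v)
      stats::filter(c(rep(v[1], k), v, rep(v[n], k)),
                    rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)[(k + 1):(k + n)])
    # keep true endpoints: smoothing must not shorten the path ends
    sm[1, ] <- coords[1, ]; sm[n, ] <- coords[n, ]
    coords <- sm
  }
  sum(sqrt(rowSums(diff(coords)^2)))
}

# Zhang-Suen thinning of a logical mask (8-connected skeleton)
skeletonize <- function(mask) {
  m <- mask
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      P2 <- mshift(m, -1, 0); P3 <- mshift(m, -1, 1); P4 <- mshift(m, 0, 1)
      P5 <- mshift(m, 1, 1);  P6 <- mshift(m, 1, 0);  P7 <- mshift(m, 1, -1)
      P8 <- mshift(m, 0, -1); P9 <- mshift(m, -1, -1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 < P3) + (P3 < P4) + (P4 < P5) + (P5 < P6) +
           (P6 < P7) + (P7 < P8) + (P8 < P9) + (P9 < P2)
      cond <- if (sub == 1) {
        !(P2 & P4 & P6) & !(P4 & P6 & P8)
      } else {
        !(P2 & P4 & P8) & !(P2 & P6 & P8)
      }
      del <- m & B >= 2 & B <= 6 & A == 1 & cond
      if (any(del)) { m[del] <- FALSE; changed <- TRUE }
    }
    if (!changed) break
  }
  m
}

# weighted skeleton graph: vertices = skeleton pixels, edges between
# 8-neighbours (1 / sqrt(2) weights); returns coords, graph, weights
.skeletonGraph <- function(sk) {
  idx <- which(sk, arr.ind = TRUE)
  n <- nrow(idx)
  key <- paste(idx[, 1], idx[, 2])
  lookup <- seq_len(n)
  names(lookup) <- key
  edges <- NULL; wts <- numeric(0)
  for (d in list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))) {
    nb <- paste(idx[, 1] + d[1], idx[, 2] + d[2])
    hit <- nb %in% key
    if (!any(hit)) next
    edges <- rbind(edges, cbind(lookup[hit], lookup[nb[hit]]))
    wts <- c(wts, rep(if (sum(abs(d)) == 2L) sqrt(2) else 1, sum(hit)))
  }
  g <- igraph::make_graph(if (is.null(edges)) integer(0) else t(edges),
                          n = n, directed = FALSE)
  list(idx = idx, g = g, w = wts)
}

#' Leaf length along the skeleton
#'
#' @param mask logical matrix, one connected leaf component.
#' @param profile a [CalibrationProfile-class] (or numeric mm-per-pixel).
#' @return length in mm.
#' @examples
#' m <- matrix(TRUE, 100, 10)           # straight 100 x 10 px blade
#' leafLength(m, 1)                     # about 100 (px units)
#' @rdname morphometrics
#' @export
leafLength <- function(mask, profile) {
  mmpp <- if (is.numeric(profile)) profile else mmPerPixel(profile)
  if (sum(mask) <= 1L) return(mmpp)
  mask <- .padMask(mask)
  dt <- distanceMap(mask)
  sk <- skeletonize(mask)
  if (sum(sk) <= 1L) return((2 * max(dt) - 0.5) * mmpp)  # blob: diameter
  sg <- .skeletonGraph(sk)
  dtv <- dt[sg$idx]
  deg <- igraph::degree(sg$g)
  ends <- which(deg <= 1L)
  if (length(ends) < 2L) {
    # cycle: double sweep from an arbitrary vertex
    d1 <- igraph::distances(sg$g, v = 1, weights = sg$w)
    v1 <- which.max(replace(d1, !is.finite(d1), -1))
    d2 <- igraph::distances(sg$g, v = v1, weights = sg$w)
    v2 <- which.max(replace(d2, !is.finite(d2), -1))
    ends <- c(v1, v2)
  }
  D <- igraph::distances(sg$g, v = ends, to = ends, weights = sg$w)
  D[!is.finite(D)] <- NA
  tot <- outer(dtv[ends], dtv[ends], "+") + D
  best <- which(tot == max(tot, na.rm = TRUE), arr.ind = TRUE)[1, ]
  v1 <- ends[best[1]]; v2 <- ends[best[2]]
  path <- igraph::shortest_paths(sg$g, from = v1, to = v2,
                                 weights = sg$w)$vpath[[1]]
  lenPx <- .smoothPathLength(sg$idx[as.integer(path), , drop = FALSE]) +
    dtv[v1] + dtv[v2]
  lenPx * mmpp
}

#' Leaf width as maximum inscribed blade width
#'
#' @rdname morphometrics
#' @export
leafWidth <- function(mask, profile) {
  mmpp <- if (is.numeric(profile)) profile else mmPerPixel(profile)
  if (sum(mask) <= 1L) return(mmpp)
  mask <- .padMask(mask)
  dt <- distanceMap(mask)
  sk <- skeletonize(mask)
  r <- if (any(sk)) max(dt[sk]) else max(dt)
  (2 * r - 0.5) * mmpp
}

#' Leaf perimeter from the smoothed contour polygon
#'
#' @param smoothWindow half-width of the circular moving average applied
#'   to the contour coordinates (default 1, i.e. window 3).
#' @rdname morphometrics
#' @export
leafPerimeter <- function(mask, profile, smoothWindow = 1L) {
  mmpp <- if (is.numeric(profile)) profile else mmPerPixel(profile)
  npx <- sum(mask)
  if (npx <= 1L) return(4 * mmpp)
  mask <- .padMask(mask)
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))[[1]]
  n <- nrow(oc)
  k <- as.integer(smoothWindow)
  if (n > 2L * (2L * k + 1L) && k > 0L) {
    oc <- apply(oc, 2, function(v) {
      ext <- c(tail(v, k), v, head(v, k))
      stats::filter(ext, rep(1 / (2 * k + 1), 2 * k + 1),
                    sides = 2)[(k + 1):(k + n)]
    })
  }
  d <- rbind(diff(oc), oc[1, ] - oc[n, ])
  sum(sqrt(rowSums(d^2))) * mmpp
}

#' Isoperimetric compactness
#'
#' `4*pi*area/perimeter^2`: 1 for a disc, smaller for elongated shapes.
#'
#' @param area leaf area (any unit).
#' @param perimeter leaf perimeter (consistent unit).
#' @return dimensionless compactness.
#' @rdname morphometrics
#' @export
leafCompactness <- function(area, perimeter) {
  stopIfNot(all(area > 0), "area must be positive")
  stopIfNot(all(perimeter > 0), "perimeter must be positive")
  4 * pi * area / perimeter^2
}

#' Dominant colour class of a leaf
#'
#' The class with the largest area within the leaf; ties break towards
#' the darker class (green-4 darkest, then green-3, green-2; yellow is
#' considered lightest). Returns `"unclassified"` if all class areas are
#' zero.
#'
#' @param classAreas named numeric vector with entries `green2`, `green3`,
#'   `green4`, `yellow` (areas or pixel counts).
#' @return class label.
#' @export
classifyLeaf <- function(classAreas) {
  order <- c("green4", "green3", "green2", "yellow")  # darkest first
  v <- classAreas[order]
  if (all(is.na(v)) || all(v == 0, na.rm = TRUE)) return("unclassified")
  order[which.max(v)]
}

#' Measure every extracted leaf
#'
#' Runs the morphometric estimators over a list of leaf objects from
#' [extractLeaves()] and returns the per-leaf record table.
#'
#' @param leaves list of leaf objects.
#' @param profile a [CalibrationProfile-class].
#' @param taskId identifier copied into the table.
#' @return data.frame with columns `task_id`, `leaf_id`, `LL_mm`, `LW_mm`,
#'   `perimeter_mm`, `area_mm2`, `compactness`, `area_g2`, `area_g3`,
#'   `area_g4`, `area_yellow`, `dominant_class`.
#' @export
measureLeaves <- function(leaves, profile, taskId = "task") {
  app <- areaPerPixel(profile)
  rows <- lapply(seq_along(leaves), function(i) {
    lf <- leaves[[i]]
    area <- lf$pixelCount * app
    per <- leafPerimeter(lf$mask, profile)
    cc <- lf$classPixelCounts
    if (length(cc) == 0L)
      cc <- c(green2 = 0, green3 = 0, green4 = 0, yellow = 0)
    data.frame(
      task_id = taskId, leaf_id = i,
      LL_mm = leafLength(lf$mask, profile),
      LW_mm = leafWidth(lf$mask, profile),
      perimeter_mm = per,
      area_mm2 = area,
      compactness = leafCompactness(area, per),
      area_g2 = cc[["green2"]] * app,
      area_g3 = cc[["green3"]] * app,
      area_g4 = cc[["green4"]] * app,
      area_yellow = cc[["yellow"]] * app,
      dominant_class = classifyLeaf(cc),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
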