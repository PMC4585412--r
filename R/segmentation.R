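#' Convert an 8-bit RGB raster to 8-bit HSL
#'
#' Hue, saturation and lightness are each quantised to 0-255: hue as
#' `round(degrees * 255/360)`, saturation and lightness as `round(x*255)`
#' of their unit-interval values. Achromatic pixels (max = min) get
#' H = 0, S = 0. Lightness is `(max+min)/2`.
#'
#' @param raster numeric array `rows x cols x 3`, RGB in 0-255.
#' @return numeric array `rows x cols x 3` with H, S, L planes in 0-255.
#' @examples
#' px <- array(c(0, 255, 0), c(1, 1, 3))
#' rgbToHsl8(px)[1, 1, ]   # H = 85 for pure green
#' @export
rgbToHsl8 <- function(raster) {
  d <- dim(raster)
  stopIfNot(length(d) == 3L && d[3] == 3L, "raster must be rows x cols x 3")
  r <- raster[, , 1, drop = FALSE] / 255
  g <- raster[, , 2, drop = FALSE] / 255
  b <- raster[, , 3, drop = FALSE] / 255
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  delta <- mx - mn
  chrom <- delta > 0
  s <- array(0, dim(l))
  denom <- 1 - abs(2 * l - 1)
  s[chrom] <- (delta / denom)[chrom]
  s[s > 1] <- 1
  h6 <- array(0, dim(l))
  isr <- chrom & mx == r
  isg <- chrom & !isr & mx == g
  isb <- chrom & !isr & !isg
  h6[isr] <- (((g - b) / delta)[isr]) %% 6
  h6[isg] <- ((b - r) / delta)[isg] + 2
  h6[isb] <- ((r - g) / delta)[isb] + 4
  out <- array(0, d)
  out[, , 1] <- round(h6 * 60 * 255 / 360)
  out[, , 2] <- round(s * 255)
  out[, , 3] <- round(l * 255)
  out
}

#' Convert 8-bit HSL values to 8-bit RGB
#'
#' Inverse of [rgbToHsl8()] up to quantisation (round trips are stable
#' within about one 8-bit step per channel). Used by the synthetic scan
#' renderer to paint leaves from HSL band centres.
#'
#' @param h,s,l numeric vectors (recycled) on the 0-255 scale.
#' @return matrix with columns r, g, b (integers 0-255).
#' @export
hsl8ToRgb <- function(h, s, l) {
  n <- max(length(h), length(s), length(l))
  h <- rep_len(h, n); s <- rep_len(s, n); l <- rep_len(l, n)
  hd <- h * 360 / 255
  sv <- s / 255
  lv <- l / 255
  c0 <- (1 - abs(2 * lv - 1)) * sv
  hp <- hd / 60
  x <- c0 * (1 - abs(hp %% 2 - 1))
  m <- lv - c0 / 2
  sector <- pmin(floor(hp), 5)
  r <- g <- b <- numeric(n)
  sel <- sector == 0; r[sel] <- c0[sel]; g[sel] <- x[sel]
  sel <- sector == 1; r[sel] <- x[sel]; g[sel] <- c0[sel]
  sel <- sector == 2; g[sel] <- c0[sel]; b[sel] <- x[sel]
  sel <- sector == 3; g[sel] <- x[sel]; b[sel] <- c0[sel]
  sel <- sector == 4; r[sel] <- x[sel]; b[sel] <- c0[sel]
  sel <- sector == 5; r[sel] <- c0[sel]; b[sel] <- x[sel]
  cbind(r = round((r + m) * 255), g = round((g + m) * 255),
        b = round((b + m) * 255))
}

#' Threshold an HSL raster with a band
#'
#' A pixel is foreground when H, S and L all lie inside the band's
#' inclusive ranges.
#'
#' @param hsl HSL raster from [rgbToHsl8()].
#' @param band a [Band-class].
#' @return logical matrix mask.
#' @export
bandMask <- function(hsl, band) {
  stopIfNot(is(band, "Band"), "band must be a Band")
  h <- hsl[, , 1]; s <- hsl[, , 2]; l <- hsl[, , 3]
  h >= band@h[1] & h <= band@h[2] &
    s >= band@s[1] & s <= band@s[2] &
    l >= band@l[1] & l <= band@l[2]
}

#' Remove small connected components (impurities)
#'
#' Dust and other specks survive colour thresholding; connected components
#' smaller than `minAreaPx` pixels are deleted, larger components are left
#' untouched. 8-connectivity by default so thin diagonal leaf tips do not
#' fragment.
#'
#' @param mask logical matrix.
#' @param minAreaPx minimum component size in pixels (default 50, about
#'   2.4 mm^2 at 0.048 mm^2/px).
#' @param connectivity 8 (default) or 4.
#' @return logical matrix with small components removed.
#' @export
removeImpurities <- function(mask, minAreaPx = 50, connectivity = 8) {
  stopIfNot(minAreaPx >= 1, "minAreaPx must be >= 1")
  stopIfNot(connectivity %in% c(4, 8), "connectivity must be 4 or 8")
  if (!any(mask) || minAreaPx == 1) return(mask)
  lab <- if (connectivity == 8) label8(mask) else {
    l4 <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
    storage.mode(l4) <- "integer"
    l4
  }
  sizes <- tabulate(lab[lab > 0L])
  keep <- which(sizes >= minAreaPx)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Class masks by intersection with the cleaned total mask
#'
#' The green-2/3/4 class masks are the raw band masks (impurities and all)
#' intersected with the impurity-cleaned total leaf mask, so specks in a
#' class band but outside real leaves never contribute to class areas.
#'
#' @param totalMask impurity-cleaned logical mask of all leaf pixels.
#' @param hsl HSL raster.
#' @param bands a [BandSet-class]; its `green2`, `green3`, `green4` (and
#'   `yellow`) bands are used.
#' @return named list of logical masks: `green2`, `green3`, `green4`,
#'   `yellow`.
#' @export
classMasks <- function(totalMask, hsl, bands) {
  stopIfNot(is(bands, "BandSet"), "bands must be a BandSet")
  lapply(
    c(green2 = "green2", green3 = "green3", green4 = "green4",
      yellow = "yellow"),
    function(nm) bandMask(hsl, slot(bands, nm)) & totalMask
  )
}

#' Total-leaf mask of an HSL raster
#'
#' Union of the green and yellow band masks (total leaf area is green plus
#' yellow leaf), before impurity removal.
#'
#' @param hsl HSL raster.
#' @param bands a [BandSet-class].
#' @return logical matrix.
#' @export
totalLeafMask <- function(hsl, bands) {
  stopIfNot(is(bands, "BandSet"), "bands must be a BandSet")
  bandMask(hsl, bands@green) | bandMask(hsl, bands@yellow)
}
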