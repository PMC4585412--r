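#' Construct an HSL threshold band
#'
#' @param name band label.
#' @param h,s,l length-2 inclusive `[min, max]` ranges on the 0-255 scale.
#' @return A [Band-class] object.
#' @examples
#' Band("green", c(39, 131), c(34, 255), c(30, 233))
#' @export
Band <- function(name, h, s = c(0, 255), l = c(0, 255)) {
  new("Band", name = as.character(name), h = as.integer(h),
      s = as.integer(s), l = as.integer(l))
}

setMethod("show", "Band", function(object) {
  cat(sprintf("Band '%s': H %d-%d  S %d-%d  L %d-%d\n", object@name,
              object@h[1], object@h[2], object@s[1], object@s[2],
              object@l[1], object@l[2]))
})

#' Construct a band set
#'
#' @param green,yellow,green2,green3,green4 [Band-class] objects; the class
#'   bands must be pairwise disjoint and contained in `green`.
#' @return A [BandSet-class] object.
#' @export
BandSet <- function(green, yellow, green2, green3, green4) {
  new("BandSet", green = green, yellow = yellow, green2 = green2,
      green3 = green3, green4 = green4)
}

#' Default segmentation bands
#'
#' The green and yellow bands are the fixed HSL thresholds of the
#' desktop-scanner reference method (green H 39-131, S 34-255, L 30-233;
#' yellow H 0-38, same S/L). The three green-class sub-bands split the
#' green band's lightness range into light (green-2, L 150-233), moderate
#' (green-3, L 90-149) and dark (green-4, L 30-89) classes; this split is
#' a documented simulation default (centres near L 180/130/80), not an
#' instrument constant, and together the class bands tile the green band.
#'
#' @return A [BandSet-class].
#' @examples
#' defaultBands()
#' @export
defaultBands <- function() {
  BandSet(
    green  = Band("green",  c(39, 131), c(34, 255), c(30, 233)),
    yellow = Band("yellow", c(0, 38),   c(34, 255), c(30, 233)),
    green2 = Band("green2", c(39, 131), c(34, 255), c(150, 233)),
    green3 = Band("green3", c(39, 131), c(34, 255), c(90, 149)),
    green4 = Band("green4", c(39, 131), c(34, 255), c(30, 89))
  )
}

setMethod("show", "BandSet", function(object) {
  cat("BandSet\n")
  for (nm in c("green", "yellow", "green2", "green3", "green4")) {
    cat("  "); show(slot(object, nm))
  }
})

#' Extract one band from a band set
#'
#' @param x a [BandSet-class].
#' @param name one of `"green"`, `"yellow"`, `"green2"`, `"green3"`,
#'   `"green4"`.
#' @return A [Band-class].
#' @export
getBand <- function(x, name) {
  stopIfNot(is(x, "BandSet"), "x must be a BandSet")
  stopIfNot(name %in% c("green", "yellow", "green2", "green3", "green4"),
            "unknown band name")
  slot(x, name)
}
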