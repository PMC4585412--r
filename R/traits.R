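#' Canonical names of the 29 per-plant traits
#'
#' Six size traits (leaf number LN; total, green, average, maximum leaf
#' area TLA/GLA/ALA/MLA; leaf-area SD LASD), seven colour traits (class
#' areas GLA2/GLA3/GLA4, class area ratios GLAR2/GLAR3/GLAR4, and the
#' area-weighted green-class score GLCC) and sixteen shape traits
#' (average/maximum/SD of leaf length, width, perimeter and compactness,
#' plus the length-to-width ratios ALWR/MLWR and the perimeter-to-area
#' ratios APAR/MPAR).
#'
#' @return character vector of the 29 trait names, size then colour then
#'   shape.
#' @export
traitNames <- function() {
  c("LN", "TLA", "GLA", "ALA", "MLA", "LASD",
    "GLA2", "GLA3", "GLA4", "GLAR2", "GLAR3", "GLAR4", "GLCC",
    "ALL", "MLL", "LLSD", "ALW", "MLW", "LWSD",
    "ALP", "MLP", "LPSD", "ALC", "MLC", "LCSD",
    "ALWR", "MLWR", "APAR", "MPAR")
}

#' Trait names grouped by category
#'
#' @return named list with elements `size` (6 traits), `colour` (7) and
#'   `shape` (16).
#' @export
traitGroups <- function() {
  nms <- traitNames()
  list(size = nms[1:6], colour = nms[7:13], shape = nms[14:29])
}

#' Aggregate per-leaf records into the 29 per-plant traits
#'
#' Averages are arithmetic means over leaves, maxima are per-leaf maxima
#' and SDs are population standard deviations (divide by n). Colour
#' ratios are class areas over GLA (`NA` when GLA is zero); the
#' green-class score is `GLCC = (2*GLA2 + 3*GLA3 + 4*GLA4)/GLA`. The
#' perimeter-to-area ratios are `APAR = ALP/ALA` and `MPAR = max` over
#' leaves of each leaf's perimeter/area.
#'
#' @param records per-leaf data.frame from [measureLeaves()] (columns
#'   `LL_mm`, `LW_mm`, `perimeter_mm`, `area_mm2`, `compactness`,
#'   `area_g2`, `area_g3`, `area_g4`, `area_yellow`).
#' @param plantId identifier for the resulting object.
#' @return A [PlantTraits-class].
#' @examples
#' rec <- data.frame(LL_mm = 100, LW_mm = 10, perimeter_mm = 220,
#'                   area_mm2 = 1000, compactness = 0.26,
#'                   area_g2 = 0, area_g3 = 1000, area_g4 = 0,
#'                   area_yellow = 0)
#' aggregateTraits(rec)
#' @export
aggregateTraits <- function(records, plantId = "plant") {
  stopIfNot(is.data.frame(records) && nrow(records) >= 1,
            "records must be a non-empty data.frame")
  popSD <- function(x) sqrt(mean((x - mean(x))^2))
  n <- nrow(records)
  areas <- records$area_mm2
  gla2 <- sum(records$area_g2); gla3 <- sum(records$area_g3)
  gla4 <- sum(records$area_g4)
  gla <- gla2 + gla3 + gla4
  par <- records$perimeter_mm / areas
  v <- c(
    LN = n, TLA = sum(areas), GLA = gla, ALA = mean(areas),
    MLA = max(areas), LASD = popSD(areas),
    GLA2 = gla2, GLA3 = gla3, GLA4 = gla4,
    GLAR2 = if (gla > 0) gla2 / gla else NA_real_,
    GLAR3 = if (gla > 0) gla3 / gla else NA_real_,
    GLAR4 = if (gla > 0) gla4 / gla else NA_real_,
    GLCC = if (gla > 0) (2 * gla2 + 3 * gla3 + 4 * gla4) / gla else NA_real_,
    ALL = mean(records$LL_mm), MLL = max(records$LL_mm),
    LLSD = popSD(records$LL_mm),
    ALW = mean(records$LW_mm), MLW = max(records$LW_mm),
    LWSD = popSD(records$LW_mm),
    ALP = mean(records$perimeter_mm), MLP = max(records$perimeter_mm),
    LPSD = popSD(records$perimeter_mm),
    ALC = mean(records$compactness), MLC = max(records$compactness),
    LCSD = popSD(records$compactness),
    ALWR = mean(records$LL_mm) / mean(records$LW_mm),
    MLWR = max(records$LL_mm) / max(records$LW_mm),
    APAR = mean(records$perimeter_mm) / mean(areas),
    MPAR = max(par))
  new("PlantTraits", plantId = as.character(plantId), values = v)
}

#' @describeIn aggregateTraits the named trait vector of a `PlantTraits`.
#' @param x a [PlantTraits-class].
#' @export
traitValues <- function(x) {
  stopIfNot(is(x, "PlantTraits"), "x must be a PlantTraits")
  x@values
}

setMethod("show", "PlantTraits", function(object) {
  cat(sprintf("PlantTraits '%s' (29 traits)\n", object@plantId))
  g <- traitGroups()
  for (nm in names(g)) {
    cat(sprintf("  %s:\n", nm))
    print(round(object@values[g[[nm]]], 3))
  }
})

#' Length x width x number leaf-area proxies
#'
#' `ALWN = ALL * ALW * LN` and `MLWN = MLL * MLW * LN`: simple products
#' that track green leaf area closely when blades are near-rectangular.
#'
#' @param traits a [PlantTraits-class] (or named vector with `ALL`,
#'   `ALW`, `MLL`, `MLW`, `LN`).
#' @return numeric scalar, mm^2 (length times width times count).
#' @export
alwn <- function(traits) {
  v <- if (is(traits, "PlantTraits")) traits@values else traits
  unname(v[["ALL"]] * v[["ALW"]] * v[["LN"]])
}

#' @rdname alwn
#' @export
mlwn <- function(traits) {
  v <- if (is(traits, "PlantTraits")) traits@values else traits
  unname(v[["MLL"]] * v[["MLW"]] * v[["LN"]])
}

#' Rectangular approximation of the perimeter-to-area ratio
#'
#' For a rectangular blade, `APAR = ALP/ALA = 2/ALW + 2/ALL`; because
#' blades are much longer than wide this tends to the limit `2/ALW`.
#' Both values are returned.
#'
#' @param ALL average leaf length, mm.
#' @param ALW average leaf width, mm.
#' @return named numeric: `rect` (2/ALW + 2/ALL) and `limit` (2/ALW),
#'   in 1/mm.
#' @examples
#' aparRectangular(100, 10)   # rect 0.22, limit 0.20
#' @export
aparRectangular <- function(ALL, ALW) {
  stopIfNot(all(ALL > 0) && all(ALW > 0), "ALL and ALW must be positive")
  c(rect = 2 / ALW + 2 / ALL, limit = 2 / ALW)
}
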