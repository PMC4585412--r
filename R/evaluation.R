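#' Method-comparison accuracy statistics
#'
#' Statistics for validating one measurement method against a reference:
#' the mean absolute per cent error
#' \deqn{MAPE = \frac{1}{n}\sum_i \frac{|x_{i,ref} - x_{i,test}|}{x_{i,ref}},}
#' the population SD of the per-sample absolute per cent errors, and the
#' squared Pearson correlation between the two methods.
#'
#' @param reference numeric vector of reference measurements (non-zero
#'   for the per cent error statistics).
#' @param test numeric vector of test measurements, same length.
#' @return `mape()` and `apeSD()` return a percentage; `rSquared()` a
#'   value in `[0, 1]` (`NA` if either vector is constant).
#' @examples
#' mape(c(100, 200), c(90, 210))   # 7.5
#' @name evaluation
NULL

.checkPairs <- function(reference, test) {
  stopIfNot(length(reference) == length(test) && length(reference) >= 1,
            "reference and test must be equal-length, non-empty")
  stopIfNot(all(is.finite(reference)) && all(is.finite(test)),
            "measurements must be finite")
  stopIfNot(all(reference != 0), "reference values must be non-zero")
}

#' @rdname evaluation
#' @export
mape <- function(reference, test) {
  .checkPairs(reference, test)
  100 * mean(abs(reference - test) / abs(reference))
}

#' @rdname evaluation
#' @export
apeSD <- function(reference, test) {
  .checkPairs(reference, test)
  ape <- 100 * abs(reference - test) / abs(reference)
  sqrt(mean((ape - mean(ape))^2))
}

#' @rdname evaluation
#' @export
rSquared <- function(reference, test) {
  stopIfNot(length(reference) == length(test) && length(reference) >= 2,
            "need at least two pairs")
  if (stats::sd(reference) == 0 || stats::sd(test) == 0) return(NA_real_)
  stats::cor(reference, test)^2
}

#' Per-class discrimination error
#'
#' For each true class, the fraction of its members assigned to a
#' different class, as a percentage. Classes with no members get `NA`
#' (not 0).
#'
#' @param trueLabels,predictedLabels character vectors of equal length.
#' @param classes class set; defaults to the classes present in
#'   `trueLabels`.
#' @return named numeric vector of percentages.
#' @examples
#' discriminationError(rep("green4", 50),
#'                     c(rep("green4", 49), "green3"))   # 2
#' @export
discriminationError <- function(trueLabels, predictedLabels,
                                classes = sort(unique(trueLabels))) {
  stopIfNot(length(trueLabels) == length(predictedLabels),
            "label vectors must have equal length")
  stopIfNot(all(trueLabels %in% classes), "unknown label in trueLabels")
  out <- vapply(classes, function(k) {
    sel <- trueLabels == k
    if (!any(sel)) return(NA_real_)
    100 * mean(predictedLabels[sel] != k)
  }, numeric(1))
  names(out) <- classes
  out
}

#' Compare measured traits against a truth table
#'
#' Convenience wrapper producing a per-trait report (MAPE, APE SD, R^2)
#' from two aligned data.frames.
#'
#' @param truth,measured data.frames with one row per plant and the trait
#'   columns to compare.
#' @param traits character vector of column names.
#' @return data.frame with columns `trait`, `n`, `MAPE`, `APE_SD`, `R2`.
#' @export
evaluateTraits <- function(truth, measured, traits) {
  stopIfNot(nrow(truth) == nrow(measured),
            "truth and measured must have one row per plant")
  rows <- lapply(traits, function(tr) {
    x <- truth[[tr]]; y <- measured[[tr]]
    stopIfNot(!is.null(x) && !is.null(y), sprintf("missing trait '%s'", tr))
    data.frame(trait = tr, n = length(x), MAPE = mape(x, y),
               APE_SD = apeSD(x, y),
               R2 = if (length(x) >= 2) rSquared(x, y) else NA_real_)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
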