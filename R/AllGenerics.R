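#' Number of retained segments per sample
#' @param x A [CNVProfiles-class] object.
#' @return Named integer vector.
#' @export
setGeneric("nSegments", function(x) standardGeneric("nSegments"))

#' Mean segment size per sample (bp)
#' @param x A [CNVProfiles-class] object.
#' @return Named numeric vector; NA for samples with no segments.
#' @export
setGeneric("meanSize", function(x) standardGeneric("meanSize"))

#' Sample identifiers
#' @param x A [CNVProfiles-class] object.
#' @return Character vector.
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' Per-sample size multisets
#' @param x A [CNVProfiles-class] object.
#' @return Named list of numeric size vectors (bp).
#' @export
setGeneric("profileSizes", function(x) standardGeneric("profileSizes"))

#' @rdname nSegments
#' @export
setMethod("nSegments", "CNVProfiles", function(x)
  vapply(x@sizes, length, integer(1)))

#' @rdname meanSize
#' @export
setMethod("meanSize", "CNVProfiles", function(x)
  vapply(x@sizes, function(s) if (length(s)) mean(s) else NA_real_,
         numeric(1)))

#' @rdname sampleIDs
#' @export
setMethod("sampleIDs", "CNVProfiles", function(x) names(x@sizes))

#' @rdname profileSizes
#' @export
setMethod("profileSizes", "CNVProfiles", function(x) x@sizes)

#' @describeIn CNVProfiles-class Number of samples.
#' @param x A CNVProfiles object.
#' @export
setMethod("length", "CNVProfiles", function(x) length(x@sizes))

#' @describeIn CNVProfiles-class Subset samples by index or name.
#' @param i Index or sample names.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "CNVProfiles", function(x, i, j, ..., drop = FALSE)
  new("CNVProfiles", sizes = x@sizes[i]))

setMethod("show", "CNVProfiles", function(object) {
  n <- length(object@sizes)
  cat("CNVProfiles with", n, "sample(s)\n")
  if (n) {
    ns <- nSegments(object)
    cat(sprintf("  segments/sample: median %d (range %d-%d)\n",
                as.integer(median(ns)), min(ns), max(ns)))
    ms <- meanSize(object)
    cat(sprintf("  mean segment size: %.1f kb (across-sample median)\n",
                median(ms, na.rm = TRUE) / 1e3))
  }
})

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:",
      object@nNonrecurrent, "non-recurrent /",
      object@nRecurrentFast, "fast-recurrent /",
      object@nRecurrentSlow, "slow-recurrent samples\n")
  cat(sprintf("  ~%.0f fragments/sample; size fold (recurrent) %.2f; seed %d\n",
              object@meanFragments, object@sizeFoldRecurrent, object@seed))
})

setMethod("show", "LSRModel", function(object) {
  cat("LSRModel [", paste(object@modalities, collapse = "+"), "]\n", sep = "")
  if (!is.na(object@delta))
    cat(sprintf("  delta = %d bp (10^%.2f)\n", as.integer(object@delta),
                object@log10Delta))
  cat(sprintf("  decision cutoff = %.4g (score >= cutoff -> positive)\n",
              object@cutoff))
})

setMethod("show", "CVSummary", function(object) {
  cat(sprintf("CVSummary: contrast '%s', modalities %s, %d repeats trim %d\n",
              object@contrast, paste(object@modalities, collapse = "+"),
              object@nRepeats, object@trim))
  m <- rbind(train = object@train, test = object@test)
  print(round(m, 4))
})

setMethod("show", "KMCurve", function(object) {
  cat(sprintf("KMCurve truncated at %g months; %d time point(s)\n",
              object@truncation, length(object@time)))
  if (length(object@time))
    cat(sprintf("  S(%g) = %.3f\n", max(object@time), min(object@surv)))
})

setMethod("show", "UTestResult", function(object) {
  cat(sprintf(
    "U test: chi2 %.3f vs %.3f, U = %.3f, p = %.3g (%g draws)\n",
    object@chi2A, object@chi2B, object@U, object@p, object@nDraws))
})
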