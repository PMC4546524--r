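#' Large size ratio (LSR) of a CNV profile
#'
#' The LSR of a sample is the fraction of its retained CNV fragments whose
#' size is at least the large-size threshold \code{delta} (membership is
#' inclusive, size >= delta). It is scale-equivariant (multiplying all sizes
#' and delta by a constant leaves it unchanged), non-increasing in delta and
#' always in [0, 1].
#'
#' @param profiles A [CNVProfiles-class] object, or a bare numeric vector of
#'   fragment sizes for a single sample.
#' @param delta Large-size threshold in bp (> 0).
#' @return Named numeric vector of LSR values in [0, 1] (a scalar for bare
#'   numeric input).
#' @details A sample with no fragments has no defined LSR; such profiles
#'   raise an error rather than returning 0, since an unmeasured genome is
#'   not evidence of small CNVs.
#' @examples
#' computeLSR(workedExampleProfile(), 31622)  # 3/7 = 0.4286
#' @export
computeLSR <- function(profiles, delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L, delta > 0)
  if (is.numeric(profiles))
    profiles <- new("CNVProfiles", sizes = list(sample = profiles))
  sizes <- profileSizes(profiles)
  empty <- vapply(sizes, length, integer(1)) == 0L
  if (any(empty))
    stop("LSR undefined for sample(s) with no segments: ",
         paste(names(sizes)[empty], collapse = ", "))
  out <- vapply(sizes, function(s) mean(s >= delta), numeric(1))
  if (length(out) == 1L && names(out) == "sample") unname(out) else out
}

#' Convert a log10 threshold to an integer bp threshold
#'
#' @param exponent Finite log10(bp) value.
#' @return \code{floor(10^exponent)} as a double holding an integer value
#'   (e.g. 4.5 -> 31622 bp; 5.7 -> 501187 bp).
#' @export
log10ToBp <- function(exponent) {
  stopifnot(is.numeric(exponent), all(is.finite(exponent)))
  floor(10^exponent)
}

#' Tune the LSR large-size threshold by maximizing AUC
#'
#' Evaluates every candidate threshold on a log10(bp) grid: at each point the
#' per-sample LSRs are computed and their AUC against the class labels is
#' measured; the threshold with maximal AUC is returned (ties broken toward
#' the smallest threshold, for determinism). The full (threshold, AUC) curve
#' is returned for plotting.
#'
#' @param profiles A [CNVProfiles-class]; every profile must be non-empty.
#' @param labels Logical (or 0/1) vector, TRUE = positive class, aligned with
#'   \code{sampleIDs(profiles)}.
#' @param grid Ordered log10(bp) candidates (default 3.3 to 6.5 by 0.1).
#' @return List: \code{log10_delta}, \code{delta} (floored bp), \code{auc} at
#'   the optimum, and \code{curve}, a data.frame (log10_delta, auc).
#' @export
optimizeDelta <- function(profiles, labels,
                          grid = seq(3.3, 6.5, by = 0.1)) {
  labels <- as.logical(labels)
  stopifnot(length(labels) == length(profiles))
  if (length(unique(labels)) < 2L)
    stop("AUC undefined: both classes must be present")
  if (is.unsorted(grid, strictly = TRUE))
    stop("threshold grid must be strictly increasing")
  aucs <- vapply(grid, function(g)
    rocAuc(computeLSR(profiles, 10^g), labels)$auc, numeric(1))
  best <- which.max(aucs)            # which.max takes the first (smallest) tie
  list(log10_delta = grid[best], delta = log10ToBp(grid[best]),
       auc = aucs[best], curve = data.frame(log10_delta = grid, auc = aucs))
}

#' Youden-optimal decision cutoff for a score
#'
#' Chooses the cutoff c maximizing the Youden index J(c) = sensitivity +
#' specificity - 1 under the rule score >= c -> positive. Candidates are the
#' observed score values and the midpoints between adjacent distinct values,
#' so a perfectly separating cutoff lands midway between the classes; ties
#' are broken toward the smallest cutoff.
#'
#' @param scores Numeric scores, higher = more positive-like.
#' @param labels Logical (or 0/1) class labels.
#' @return List: \code{cutoff}, \code{youden}.
#' @export
fitCutoff <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores))
  if (length(unique(labels)) < 2L)
    stop("cutoff undefined: both classes must be present")
  v <- sort(unique(scores))
  cand <- if (length(v) > 1L) sort(c(v, (v[-1] + v[-length(v)]) / 2)) else v
  youden <- vapply(cand, function(ct) {
    pred <- scores >= ct
    sens <- mean(pred[labels]); spec <- mean(!pred[!labels])
    sens + spec - 1
  }, numeric(1))
  best <- which.max(youden)
  list(cutoff = cand[best], youden = youden[best])
}
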