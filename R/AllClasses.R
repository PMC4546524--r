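#' CNVProfiles: per-sample multisets of filtered CNV segment sizes
#'
#' A light container holding, for each sample, the sizes (bp) of its retained
#' CNV segments. Built from a segment \code{GRanges} by [buildProfiles()];
#' consumed by [computeLSR()] and the model-fitting layer.
#'
#' @slot sizes Named list; one numeric vector of segment sizes (bp) per sample.
#' @seealso [buildProfiles()], [computeLSR()], [nSegments()], [meanSize()]
#' @export
setClass("CNVProfiles", representation(sizes = "list"))

setValidity("CNVProfiles", function(object) {
  s <- object@sizes
  if (length(s) && is.null(names(s)))
    return("profile list must be named by sample")
  if (anyDuplicated(names(s)))
    return("duplicated sample identifiers")
  bad <- vapply(s, function(x) !is.numeric(x) || any(x < 1), logical(1))
  if (any(bad))
    return(paste0("non-numeric or sub-1bp sizes for sample(s): ",
                  paste(names(s)[bad], collapse = ", ")))
  TRUE
})

#' CohortSpec: parameters of the synthetic cohort generator
#'
#' Describes one simulated radical-prostatectomy cohort: class sizes, the
#' negative-binomial CNV fragment-count model, the log-normal fragment-size
#' model with its recurrent-class large-size mixture component, covariate
#' effect strengths, event-time hazards and censoring. Construct with
#' [cohortSpec()], which documents the defaults; consume with
#' [generateCohort()].
#'
#' @slot nNonrecurrent,nRecurrentFast,nRecurrentSlow Class sizes.
#' @slot meanFragments Mean retained CNV fragments per genome.
#' @slot dispersion Negative-binomial size parameter for fragment counts.
#' @slot sizeLog10Mean Mean of log10 fragment size, non-recurrent arm.
#' @slot sizeLog10SD SD of log10 fragment size (both mixture components).
#' @slot sizeFoldRecurrent Target recurrent/non-recurrent arm mean-size ratio.
#' @slot mixtureProb Mean per-patient probability that a recurrent-arm
#'   fragment comes from the inflated component.
#' @slot baseMixtureProb Mean inflated-component probability in the
#'   non-recurrent arm (germline large fragments occur there too).
#' @slot mixtureConcentration Beta concentration of the per-patient mixture
#'   weights; smaller = more patient-to-patient burden heterogeneity.
#' @slot covariateEffects Named numeric, strengths in `[0, 1]`-ish scale for
#'   gleason, nomogram, fusion class separation (0 = null).
#' @slot medianTimeFast,medianTimeSlow Median months to recurrence per class.
#' @slot censorTime Administrative censoring horizon (months).
#' @slot decoyFraction Extra fraction of fragments that violate a filter rule.
#' @slot seed Master seed; all randomness derives from it.
#' @export
setClass("CohortSpec", representation(
  nNonrecurrent = "integer", nRecurrentFast = "integer",
  nRecurrentSlow = "integer",
  meanFragments = "numeric", dispersion = "numeric",
  sizeLog10Mean = "numeric", sizeLog10SD = "numeric",
  sizeFoldRecurrent = "numeric", mixtureProb = "numeric",
  baseMixtureProb = "numeric", mixtureConcentration = "numeric",
  covariateEffects = "numeric",
  medianTimeFast = "numeric", medianTimeSlow = "numeric",
  censorTime = "numeric", decoyFraction = "numeric",
  seed = "integer"))

setValidity("CohortSpec", function(object) {
  if (any(c(object@nNonrecurrent, object@nRecurrentFast,
            object@nRecurrentSlow) < 0))
    return("class counts must be >= 0")
  if (object@sizeFoldRecurrent < 1)
    return("sizeFoldRecurrent must be >= 1")
  if (object@mixtureProb <= 0 || object@mixtureProb > 1)
    return("mixtureProb must be in (0, 1]")
  if (object@baseMixtureProb < 0 || object@baseMixtureProb >= object@mixtureProb)
    return("baseMixtureProb must be in [0, mixtureProb)")
  if (object@sizeFoldRecurrent > 1 &&
      object@mixtureProb <= object@sizeFoldRecurrent * object@baseMixtureProb)
    return("mixtureProb must exceed sizeFoldRecurrent * baseMixtureProb")
  if (object@mixtureConcentration <= 0)
    return("mixtureConcentration must be positive")
  if (object@meanFragments <= 0 || object@dispersion <= 0)
    return("fragment-count parameters must be positive")
  if (object@decoyFraction < 0 || object@decoyFraction > 1)
    return("decoyFraction must be in [0, 1]")
  need <- c("gleason", "nomogram", "fusion")
  if (!all(need %in% names(object@covariateEffects)))
    return("covariateEffects must name gleason, nomogram and fusion")
  TRUE
})

#' LSRModel: a fitted large-size-ratio scorer
#'
#' Holds the tuned large-size threshold (delta, bp), the Youden-optimal
#' decision cutoff on the model score, the discriminant weights when several
#' modalities are combined, and the threshold/AUC tuning curve.
#'
#' @slot modalities Character subset of c("L","N","F","G").
#' @slot log10Delta,delta Tuned threshold as log10(bp) and floored bp
#'   (NA when "L" absent).
#' @slot weights Named numeric discriminant weights (length 1 for a single
#'   modality).
#' @slot offset Numeric intercept of the discriminant score.
#' @slot cutoff Decision cutoff on the score; score >= cutoff predicts the
#'   positive (recurrent-like) class.
#' @slot deltaCurve data.frame with columns log10_delta, auc.
#' @export
setClass("LSRModel", representation(
  modalities = "character", log10Delta = "numeric", delta = "numeric",
  weights = "numeric", offset = "numeric", cutoff = "numeric",
  deltaCurve = "data.frame"))

#' CVSummary: trimmed repeated two-fold cross-validation summary
#'
#' @slot contrast One of "recurrence", "fast", "lethal".
#' @slot modalities Character subset of c("L","N","F","G").
#' @slot train,test Named numeric vectors of trim-averaged metrics
#'   (accuracy, balanced_accuracy, sensitivity, specificity, youden, auc,
#'   roc_p [geometric mean]).
#' @slot splits data.frame of per-repeat metrics (train/test blocks).
#' @slot retained Integer ids of repeats kept after trimming.
#' @slot representative Integer id of the retained repeat whose metric vector
#'   is closest (Euclidean) to the trimmed average.
#' @slot nRepeats,trim Protocol parameters.
#' @export
setClass("CVSummary", representation(
  contrast = "character", modalities = "character",
  train = "numeric", test = "numeric", splits = "data.frame",
  retained = "integer", representative = "integer",
  nRepeats = "integer", trim = "integer"))

#' KMCurve: a truncated Kaplan-Meier product-limit curve
#'
#' @slot time Event/censoring times (months), ordered, within the truncation
#'   horizon.
#' @slot surv Survival estimates at \code{time} (non-increasing, starts <= 1).
#' @slot nRisk At-risk counts at \code{time}.
#' @slot nEvent Event counts at \code{time}.
#' @slot truncation Truncation horizon in months.
#' @export
setClass("KMCurve", representation(
  time = "numeric", surv = "numeric", nRisk = "numeric", nEvent = "numeric",
  truncation = "numeric"))

setValidity("KMCurve", function(object) {
  if (is.unsorted(object@time)) return("times must be ordered")
  if (any(diff(object@surv) > 1e-12)) return("survival must be non-increasing")
  if (length(object@time) && max(object@time) > object@truncation + 1e-9)
    return("times exceed the truncation horizon")
  TRUE
})

#' UTestResult: Monte-Carlo comparison of two log-rank statistics
#'
#' The test statistic is U = |chi2_a - chi2_b|; its null is the absolute
#' difference of two independent chi-squared(1) variables, sampled
#' \code{nDraws} times. p uses the add-one estimator (k + 1) / (n + 1).
#'
#' @slot chi2A,chi2B The two log-rank chi-squared statistics.
#' @slot U Absolute difference.
#' @slot nDraws Number of Monte-Carlo draws.
#' @slot p Estimated p-value in (0, 1].
#' @slot seed Seed used for the draws.
#' @export
setClass("UTestResult", representation(
  chi2A = "numeric", chi2B = "numeric", U = "numeric",
  nDraws = "numeric", p = "numeric", seed = "integer"))
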