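#' Binary Gleason-grade encoding
#'
#' Dichotomizes the Gleason score at the conventional high-grade boundary:
#' 0 for scores of 7 or less, 1 for scores above 7.
#'
#' @param score Integer Gleason score(s) in 2..10.
#' @return Integer 0/1 vector.
#' @export
encodeGleason <- function(score) {
  stopifnot(is.numeric(score))
  if (any(is.na(score) | score < 2 | score > 10 | score != floor(score)))
    stop("Gleason score must be an integer in 2..10")
  as.integer(score > 7)
}

#' Binary fusion-transcript encoding
#'
#' 0 when none of the eight assayed fusion transcripts was detected, 1 when
#' one or more were.
#'
#' @param count Integer count(s) of detected fusion transcripts, 0..8.
#' @return Integer 0/1 vector.
#' @export
encodeFusion <- function(count) {
  stopifnot(is.numeric(count))
  if (any(is.na(count) | count < 0 | count > 8 | count != floor(count)))
    stop("fusion count must be an integer in 0..8")
  as.integer(count >= 1)
}

#' Assemble a feature matrix for the requested modalities
#'
#' Builds one row per sample with exactly the requested modality columns:
#' \code{L} the large size ratio, \code{N} the nomogram risk (1 minus the
#' 7-year progression-free probability, so that every feature is oriented
#' higher = more likely recurrent), \code{F} the binary fusion status and
#' \code{G} the binary high-Gleason flag. Samples missing any requested
#' modality are excluded with a message (count reported), never silently.
#'
#' @param clinical Clinical data.frame from [readClinical()] /
#'   [generateCohort()].
#' @param lsrScores Named numeric LSR per sample (required iff "L" is
#'   requested).
#' @param modalities Character subset of c("L", "N", "F", "G").
#' @return data.frame with rownames = sample ids and one column per requested
#'   modality, in L, N, F, G order.
#' @export
assembleFeatures <- function(clinical, lsrScores = NULL,
                             modalities = c("L", "N", "F", "G")) {
  modalities <- intersect(c("L", "N", "F", "G"), modalities)
  if (!length(modalities)) stop("at least one modality must be requested")
  feat <- data.frame(row.names = clinical$sample)
  if ("L" %in% modalities) {
    if (is.null(lsrScores)) stop("modality 'L' requested but no LSR scores")
    feat$L <- unname(lsrScores[clinical$sample])
  }
  if ("N" %in% modalities) feat$N <- 1 - clinical$nomogram_prob
  if ("F" %in% modalities) feat$F <- as.numeric(encodeFusion(clinical$fusion_count))
  if ("G" %in% modalities) feat$G <- as.numeric(encodeGleason(clinical$gleason))
  keep <- complete.cases(feat)
  if (!all(keep))
    message(sum(!keep), " sample(s) lacking a requested modality excluded")
  feat <- feat[keep, , drop = FALSE]
  if (!nrow(feat)) stop("no sample carries all requested modalities")
  feat
}
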