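#' Construct a synthetic cohort specification
#'
#' The defaults reproduce the reported structure of the study cohort this
#' package targets: 35 non-recurrent (followed 90+ months), 55 fast-recurrent
#' (PSADT <= 4 months) and 53 slow-recurrent (PSADT >= 15 months) patients,
#' about 152 retained CNV fragments per genome, log-normal fragment sizes with
#' a non-recurrent arm mean near 55 kb (cohort-wide mean near 147 kb), and a
#' recurrent-arm mean-size inflation of 3.2-fold produced by an upper-tail
#' mixture component. Variances, covariate effect strengths and hazards are
#' generator assumptions (the source cohort reports none); see the methods
#' vignette.
#'
#' @param nNonrecurrent,nRecurrentFast,nRecurrentSlow Class sizes
#'   (defaults 35 / 55 / 53).
#' @param meanFragments Mean retained CNV fragments per genome (default 152).
#' @param dispersion Negative-binomial size parameter for fragment counts
#'   (default 20; larger = closer to Poisson).
#' @param sizeLog10Mean Mean log10 fragment size in the non-recurrent arm
#'   (default 4.11; with the default SD and mixture this puts the
#'   non-recurrent arm's arithmetic-mean size near 55 kb and the design-mix
#'   cohort-wide mean near 147 kb).
#' @param sizeLog10SD SD of log10 fragment size (default 0.5).
#' @param sizeFoldRecurrent Recurrent / non-recurrent arm mean-size ratio
#'   (default 3.2). The inflated mixture component's location is solved
#'   analytically so the arm-mean ratio equals this value exactly.
#' @param mixtureProb Mean per-patient probability that a recurrent-arm
#'   fragment is drawn from the inflated component (default 0.25).
#' @param baseMixtureProb Mean inflated-component probability among
#'   non-recurrent patients (default 0.05): large germline fragments occur in
#'   both arms, just less often without recurrence.
#' @param mixtureConcentration Beta concentration of the per-patient mixture
#'   weights (default 4). Patients differ in large-fragment burden; this is
#'   what keeps the LSR's discrimination at a realistic level (single-modality
#'   AUC in the 0.7-0.8 range) rather than perfect.
#' @param covariateEffects Named numeric strengths (0 = no class separation)
#'   for \code{gleason}, \code{nomogram}, \code{fusion}.
#' @param medianTimeFast,medianTimeSlow Median months to recurrence
#'   (defaults 10 and 30).
#' @param censorTime Administrative censoring horizon in months (default 120;
#'   non-recurrent follow-up is drawn in [90, censorTime]).
#' @param decoyFraction Extra fraction of fragments that deliberately violate
#'   exactly one retention rule, exercising [filterSegments()] (default 0.15).
#' @param seed Master seed (default 1).
#' @return A validated [CohortSpec-class] object.
#' @seealso [generateCohort()], [expectedMeanSizes()]
#' @export
cohortSpec <- function(nNonrecurrent = 35L, nRecurrentFast = 55L,
                       nRecurrentSlow = 53L,
                       meanFragments = 152, dispersion = 20,
                       sizeLog10Mean = 4.11, sizeLog10SD = 0.5,
                       sizeFoldRecurrent = 3.2, mixtureProb = 0.25,
                       baseMixtureProb = 0.05, mixtureConcentration = 4,
                       covariateEffects = c(gleason = 1, nomogram = 1,
                                            fusion = 1),
                       medianTimeFast = 10, medianTimeSlow = 30,
                       censorTime = 120, decoyFraction = 0.15,
                       seed = 1L) {
  new("CohortSpec",
      nNonrecurrent = as.integer(nNonrecurrent),
      nRecurrentFast = as.integer(nRecurrentFast),
      nRecurrentSlow = as.integer(nRecurrentSlow),
      meanFragments = meanFragments, dispersion = dispersion,
      sizeLog10Mean = sizeLog10Mean, sizeLog10SD = sizeLog10SD,
      sizeFoldRecurrent = sizeFoldRecurrent, mixtureProb = mixtureProb,
      baseMixtureProb = baseMixtureProb,
      mixtureConcentration = mixtureConcentration,
      covariateEffects = covariateEffects,
      medianTimeFast = medianTimeFast, medianTimeSlow = medianTimeSlow,
      censorTime = censorTime, decoyFraction = decoyFraction,
      seed = as.integer(seed))
}

# model fragments are drawn above the standard 2 kb retention bound, so the
# fragment-count model is a model of *retained* fragments
.minSizeLog10 <- log10(2000)

# arithmetic mean of 10^x with x ~ Normal(m, s) truncated below at a
.truncLog10Mean <- function(m, s, a = .minSizeLog10) {
  c_ <- log(10)
  10^m * exp((c_ * s)^2 / 2) *
    pnorm((m + c_ * s^2 - a) / s) / pnorm((m - a) / s)
}

# log10 offset of the inflated component so the recurrent/non-recurrent
# arm-mean ratio is exactly `fold`. With per-patient mixture weights of mean
# mu_r (recurrent) and mu_0 (non-recurrent) and component means MB (base)
# and MI (inflated, both 2 kb-truncated):
#   fold = ((1 - mu_r) MB + mu_r MI) / ((1 - mu_0) MB + mu_0 MI)
#   =>  MI = MB (fold (1 - mu_0) - (1 - mu_r)) / (mu_r - fold mu_0)
# solved for the offset by a short fixed point on the truncation factor
.mixtureOffset <- function(spec) {
  fold <- spec@sizeFoldRecurrent
  mu0 <- spec@baseMixtureProb; mur <- spec@mixtureProb
  if (fold == 1) return(0)
  m <- spec@sizeLog10Mean; s <- spec@sizeLog10SD
  MB <- .truncLog10Mean(m, s)
  MI <- MB * (fold * (1 - mu0) - (1 - mur)) / (mur - fold * mu0)
  off <- log10(MI / MB)
  for (i in 1:6)
    off <- off + log10(MI / .truncLog10Mean(m + off, s))
  off
}

#' Closed-form expected fragment sizes per arm
#'
#' Expected arithmetic-mean fragment size (bp) of the generator's size model
#' for each arm; the recurrent/non-recurrent ratio equals
#' \code{sizeFoldRecurrent} by construction. Used as the analytic reference
#' in the package's law-of-large-numbers checks.
#'
#' @param spec A [CohortSpec-class].
#' @return Named numeric: \code{nonrecurrent}, \code{recurrent}.
#' @export
expectedMeanSizes <- function(spec) {
  off <- .mixtureOffset(spec)
  MB <- .truncLog10Mean(spec@sizeLog10Mean, spec@sizeLog10SD)
  MI <- .truncLog10Mean(spec@sizeLog10Mean + off, spec@sizeLog10SD)
  mu0 <- spec@baseMixtureProb
  nonrec <- (1 - mu0) * MB + mu0 * MI
  c(nonrecurrent = nonrec, recurrent = nonrec * spec@sizeFoldRecurrent)
}

# truncated-normal draw of log10 sizes above the retention bound
.rlog10Size <- function(n, m, s) {
  lo <- pnorm((.minSizeLog10 - m) / s)
  qnorm(runif(n, lo, 1)) * s + m
}

# one sample's fragment block; everything drawn inside the caller's RNG stream
.sampleSegments <- function(spec, id, recurrent) {
  n <- max(1L, rnbinom(1L, size = spec@dispersion, mu = spec@meanFragments))
  mu <- if (recurrent) spec@mixtureProb else spec@baseMixtureProb
  kap <- spec@mixtureConcentration
  piSample <- if (mu <= 0) 0 else rbeta(1, kap * mu, kap * (1 - mu))
  comp <- runif(n) < piSample
  lsz <- .rlog10Size(n, spec@sizeLog10Mean + .mixtureOffset(spec) * comp,
                     spec@sizeLog10SD)
  size <- round(10^lsz)
  markers <- pmax(10L, as.integer(round(size / 1500 * runif(n, 0.7, 1.3))))
  pval <- runif(n, 0, 0.001)
  nDecoy <- rbinom(1L, n, spec@decoyFraction)
  if (nDecoy > 0) {
    # decoys violate exactly one retention rule; size-passing decoys draw
    # from the sample's own mixture so filtering leaves the size model intact
    mode <- sample.int(3L, nDecoy, replace = TRUE)
    dcomp <- runif(nDecoy) < piSample
    dsize <- ifelse(mode == 1L, round(runif(nDecoy, 100, 1999)),
                    round(10^.rlog10Size(
                      nDecoy,
                      spec@sizeLog10Mean + .mixtureOffset(spec) * dcomp,
                      spec@sizeLog10SD)))
    dmark <- ifelse(mode == 2L, sample(1:9, nDecoy, replace = TRUE),
                    pmax(10L, as.integer(round(dsize / 1500))))
    dp <- ifelse(mode == 3L, runif(nDecoy, 0.001, 1),
                 runif(nDecoy, 0, 0.001))
    size <- c(size, dsize); markers <- c(markers, as.integer(dmark))
    pval <- c(pval, dp)
    n <- n + nDecoy
  }
  # fixed seqlevel universe so per-sample GRanges concatenate silently
  chrom <- factor(paste0("chr", sample.int(22L, n, replace = TRUE)),
                  levels = paste0("chr", 1:22))
  start <- round(runif(n, 1e4, 1.4e8))
  state <- sample(c("loss", "gain"), n, replace = TRUE, prob = c(0.58, 0.42))
  GRanges(chrom, IRanges(start + 1, start + size),
          sample = rep(id, n), markers = markers,
          state = factor(state, levels = c("loss", "gain")), pvalue = pval)
}

# inverse-CDF draw from an exponential truncated to (0, cap]
.rtruncExp <- function(n, rate, cap) {
  -log(1 - runif(n) * (1 - exp(-rate * cap))) / rate
}

#' Generate a synthetic cohort
#'
#' Draws one cohort from a [CohortSpec-class]: a CNV segment table (with a
#' controlled fraction of filter-violating decoy fragments) and a clinical
#' table with recurrence status, follow-up, PSADT, Gleason score, nomogram
#' 7-year progression-free probability and fusion-transcript count, all with
#' class-dependent distributions. Fully reproducible: all randomness flows
#' from \code{spec@seed}, through one derived sub-stream per sample, so the
#' same spec yields byte-identical tables.
#'
#' @param spec A [CohortSpec-class].
#' @return List with \code{segments} (a \code{GRanges} in [readSegments()]
#'   layout) and \code{clinical} (a data.frame in [readClinical()] layout,
#'   including the derived \code{eligible_nonrecurrent} flag).
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  nTot <- spec@nNonrecurrent + spec@nRecurrentFast + spec@nRecurrentSlow
  if (nTot == 0L) stop("cohort spec requests zero samples")
  cls <- rep(c("nonrec", "fast", "slow"),
             c(spec@nNonrecurrent, spec@nRecurrentFast, spec@nRecurrentSlow))
  ids <- sprintf("S%04d", seq_len(nTot))
  set.seed(spec@seed)
  subSeeds <- sample.int(.Machine$integer.max, nTot)
  z <- c(nonrec = 0, slow = 1, fast = 1.3)[cls]   # latent class risk
  eg <- spec@covariateEffects[["gleason"]]
  en <- spec@covariateEffects[["nomogram"]]
  ef <- spec@covariateEffects[["fusion"]]
  segs <- vector("list", nTot)
  clin <- vector("list", nTot)
  for (i in seq_len(nTot)) {
    set.seed(subSeeds[i])
    rec <- cls[i] != "nonrec"
    segs[[i]] <- .sampleSegments(spec, ids[i], rec)
    gl <- min(10L, max(2L, as.integer(round(rnorm(1, 6.3 + 0.5 * eg * z[i],
                                                  1.1)))))
    m <- min(0.98, max(0.02, 0.80 - 0.12 * en * z[i]))
    nom <- rbeta(1, m * 8, (1 - m) * 8)
    qFus <- 1 / (1 + exp(0.8 - 0.9 * ef * z[i]))
    fus <- if (runif(1) < qFus) 1L + rbinom(1, 7, 0.15) else 0L
    if (rec) {
      med <- if (cls[i] == "fast") spec@medianTimeFast else spec@medianTimeSlow
      fup <- .rtruncExp(1, log(2) / med, spec@censorTime)
      psadt <- if (cls[i] == "fast") runif(1, 1, 4) else runif(1, 15, 40)
    } else {
      fup <- runif(1, 90, spec@censorTime)
      psadt <- NA_real_
    }
    clin[[i]] <- data.frame(
      sample = ids[i], recurrent = rec, followup_months = round(fup, 2),
      psadt_months = round(psadt, 2), gleason = gl,
      nomogram_prob = round(nom, 4), fusion_count = fus,
      stringsAsFactors = FALSE)
  }
  clinical <- do.call(rbind, clin)
  clinical$eligible_nonrecurrent <-
    !clinical$recurrent & clinical$followup_months >= 90
  list(segments = do.call(c, segs), clinical = clinical)
}

#' Write a generated cohort to disk
#'
#' @param cohort List from [generateCohort()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the two paths, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- file.path(dir, "segments.tsv")
  cp <- file.path(dir, "clinical.csv")
  writeSegments(cohort$segments, sp)
  writeClinical(cohort$clinical, cp)
  invisible(c(segments = sp, clinical = cp))
}

#' The documented 7-fragment worked-example profile
#'
#' A fixed single-sample profile of seven CNV fragments of which exactly three
#' reach the 31622 bp (10^4.5) large-size threshold, so its large size ratio
#' at that threshold is 3/7 = 0.43 (2 d.p.). Used in examples and as the
#' package's canonical LSR fixture.
#'
#' @return A [CNVProfiles-class] with one sample ("example") of 7 fragments.
#' @examples
#' computeLSR(workedExampleProfile(), log10ToBp(4.5))  # 3/7
#' @export
workedExampleProfile <- function() {
  new("CNVProfiles", sizes = list(
    example = c(4000, 9000, 15000, 26000, 52000, 210000, 640000)))
}
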