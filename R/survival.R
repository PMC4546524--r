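#' Kaplan-Meier estimate truncated at a follow-up horizon
#'
#' Product-limit estimator with administrative truncation: any observation
#' (event or censoring) beyond \code{truncation} months is censored at the
#' horizon, so the curve is defined only up to it.
#'
#' @param times Follow-up times in months (>= 0).
#' @param events Logical or 0/1 event indicators (TRUE = recurrence observed).
#' @param truncation Horizon in months (default 90).
#' @return A [KMCurve-class].
#' @export
kmEstimate <- function(times, events, truncation = 90) {
  stopifnot(length(times) == length(events), all(times >= 0))
  if (!length(times)) stop("no observations")
  events <- as.logical(events)
  over <- times > truncation
  events[over] <- FALSE
  times[over] <- truncation
  f <- survfit(Surv(times, events) ~ 1)
  new("KMCurve", time = f$time, surv = f$surv, nRisk = as.numeric(f$n.risk),
      nEvent = as.numeric(f$n.event), truncation = truncation)
}

#' Survival probability of a KM curve at a time point
#'
#' @param curve A [KMCurve-class].
#' @param t Time in months (<= truncation).
#' @return Step-function value S(t); 1 before the first event.
#' @export
survivalAt <- function(curve, t) {
  stopifnot(t <= curve@truncation + 1e-9)
  i <- findInterval(t, curve@time)
  if (i == 0) 1 else curve@surv[i]
}

#' Two-group log-rank test with truncated follow-up
#'
#' Applies the same truncation rule as [kmEstimate()] to both groups, then
#' the standard two-group log-rank chi-squared statistic (1 df).
#'
#' @param times,events As in [kmEstimate()].
#' @param group Two-level factor/logical separating the groups.
#' @param truncation Horizon in months (default 90).
#' @return List: \code{chi2}, \code{p} (both groups must be non-empty).
#' @export
logrankTest <- function(times, events, group, truncation = 90) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2L)
    stop("log-rank needs exactly two non-empty groups")
  events <- as.logical(events)
  over <- times > truncation
  events[over] <- FALSE
  times[over] <- truncation
  sd <- survdiff(Surv(times, events) ~ group)
  chi2 <- unname(sd$chisq)
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Monte-Carlo U test comparing two log-rank statistics
#'
#' Tests whether two risk models separate survival curves differently:
#' U = |chi2_a - chi2_b|, referred to the null distribution of the absolute
#' difference of two independent chi-squared(1) variables, sampled
#' \code{nDraws} times (default 10^7). The p-value uses the add-one estimator
#' (k + 1) / (n + 1), which cannot return an exact zero. The independence
#' assumption between the two models' statistics is inherited from the
#' testing protocol this package implements, not endorsed: models evaluated
#' on the same patients are typically positively dependent.
#'
#' @param chi2A,chi2B Non-negative log-rank chi-squared statistics.
#' @param nDraws Monte-Carlo draws (default 1e7).
#' @param seed Integer seed for the draws.
#' @return A [UTestResult-class].
#' @export
uTest <- function(chi2A, chi2B, nDraws = 1e7, seed = 1L) {
  stopifnot(chi2A >= 0, chi2B >= 0, nDraws >= 1)
  U <- abs(chi2A - chi2B)
  set.seed(seed)
  k <- 0
  left <- nDraws
  while (left > 0) {
    m <- min(left, 1e6)
    k <- k + sum(abs(rchisq(m, 1) - rchisq(m, 1)) >= U)
    left <- left - m
  }
  new("UTestResult", chi2A = chi2A, chi2B = chi2B, U = U,
      nDraws = nDraws, p = (k + 1) / (nDraws + 1), seed = as.integer(seed))
}

#' Cross-fitted risk-group assignment for survival comparison
#'
#' Splits the contrast samples once into two equal halves, trains the model on
#' each half and predicts the other, so every patient receives exactly one
#' out-of-fold prediction; the merged predictions define the high/low risk
#' groups compared by [logrankTest()]. Exception: the Gleason-only model uses
#' the single global high-grade threshold (> 7) on all samples, with no
#' cross-fitting, since its cutoff involves no tuning.
#'
#' @inheritParams runSplit
#' @return data.frame: \code{sample}, \code{predicted} (TRUE = high risk),
#'   \code{followup_months}, \code{recurrent}, \code{label} (the contrast's
#'   positive-class indicator).
#' @export
mergedCvGroups <- function(profiles, clinical, contrast, modalities, seed,
                           grid = seq(3.3, 6.5, by = 0.1)) {
  dat <- .contrastData(profiles, clinical, contrast, modalities)
  cl <- dat$clinical
  if (identical(sort(modalities), "G")) {
    pred <- encodeGleason(cl$gleason) == 1L
  } else {
    n <- nrow(cl)
    set.seed(seed)
    for (attempt in seq_len(100L)) {
      perm <- sample.int(n)
      h1 <- sort(perm[seq_len(n %/% 2)]); h2 <- sort(perm[-seq_len(n %/% 2)])
      ok <- length(unique(dat$labels[h1])) == 2L &&
        length(unique(dat$labels[h2])) == 2L
      if (ok) break
      if (attempt == 100L) stop("could not draw a split with both classes")
    }
    pred <- logical(n)
    for (roles in list(list(tr = h1, te = h2), list(tr = h2, te = h1))) {
      model <- .trainHalf(profiles, cl[roles$tr, , drop = FALSE],
                          dat$labels[roles$tr], modalities, grid)
      sc <- .applyModel(model, profiles, cl[roles$te, , drop = FALSE])
      pred[roles$te] <- sc >= model@cutoff
    }
  }
  data.frame(sample = cl$sample, predicted = pred,
             followup_months = cl$followup_months, recurrent = cl$recurrent,
             label = dat$labels, stringsAsFactors = FALSE)
}

#' Survival comparison of predicted risk groups
#'
#' Given merged cross-fitted predictions ([mergedCvGroups()]), compares
#' recurrence-free survival between the predicted high- and low-risk groups:
#' truncated KM curves per group, the log-rank test, and the 90-month
#' (horizon) survival per group both as the KM estimate and as the raw
#' event-free fraction.
#'
#' @param groups data.frame from [mergedCvGroups()].
#' @param truncation Horizon in months (default 90).
#' @return List: \code{kmHigh}, \code{kmLow} ([KMCurve-class]), \code{chi2},
#'   \code{p}, and \code{survivalRates}, a data.frame (group, km, raw).
#' @export
riskGroupSurvival <- function(groups, truncation = 90) {
  if (length(unique(groups$predicted)) < 2L)
    stop("all patients predicted into one risk group")
  lr <- logrankTest(groups$followup_months, groups$recurrent,
                    groups$predicted, truncation)
  kmFor <- function(sel)
    kmEstimate(groups$followup_months[sel], groups$recurrent[sel], truncation)
  kmH <- kmFor(groups$predicted); kmL <- kmFor(!groups$predicted)
  rawFor <- function(sel)
    mean(!(groups$recurrent[sel] &
             groups$followup_months[sel] <= truncation))
  list(kmHigh = kmH, kmLow = kmL, chi2 = lr$chi2, p = lr$p,
       survivalRates = data.frame(
         group = c("high", "low"),
         km = c(survivalAt(kmH, truncation), survivalAt(kmL, truncation)),
         raw = c(rawFor(groups$predicted), rawFor(!groups$predicted))))
}
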