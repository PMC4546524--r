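#' ROC curve and AUC by rank statistics
#'
#' The AUC is the Mann-Whitney pair probability P(score+ > score-) +
#' P(tie) / 2, computed from midranks, so it is invariant under any strictly
#' monotone transform of the scores. ROC points are generated by sweeping the
#' decision threshold over the distinct observed scores.
#'
#' @param scores Numeric scores, higher = more positive-like.
#' @param labels Logical (or 0/1) class labels; both classes required.
#' @return List: \code{auc}, and \code{points}, a data.frame (threshold, fpr,
#'   tpr) from (0,0) to (1,1).
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: both classes must be present")
  r <- rank(scores)                      # midranks handle ties
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- data.frame(
    threshold = c(Inf, thr),
    fpr = c(0, vapply(thr, function(t) mean(scores[!labels] >= t), 0)),
    tpr = c(0, vapply(thr, function(t) mean(scores[labels] >= t), 0)))
  list(auc = auc, points = pts)
}

#' One-sided p-value for AUC > 0.5
#'
#' Tests whether a score ranks positives above negatives better than chance
#' (the ROC curve against the diagonal). The default is the normal
#' approximation to the Mann-Whitney statistic with midrank tie correction
#' and continuity correction; \code{method = "exact"} uses the exact
#' Mann-Whitney null distribution for tie-free scores and full enumeration of
#' label arrangements otherwise (feasible up to a few hundred thousand
#' arrangements, e.g. both classes <= 12 with ties only in smaller sets).
#'
#' @param scores,labels As in [rocAuc()].
#' @param method "normal" (default) or "exact".
#' @return p-value in (0, 1].
#' @export
rocPvalue <- function(scores, labels, method = c("normal", "exact")) {
  method <- match.arg(method)
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels); N <- n1 + n0
  if (n1 == 0L || n0 == 0L)
    stop("ROC p-value undefined: both classes must be present")
  r <- rank(scores)
  U <- sum(r[labels]) - n1 * (n1 + 1) / 2
  if (method == "exact") {
    if (!anyDuplicated(scores))
      return(stats::pwilcox(U - 1, n1, n0, lower.tail = FALSE))
    nArr <- choose(N, n1)
    if (nArr > 2.5e5)
      stop("exact enumeration infeasible for ", nArr,
           " arrangements with tied scores")
    idx <- utils::combn(N, n1)
    Uperm <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
    return(mean(Uperm >= U))
  }
  ties <- table(scores)
  tieAdj <- sum(ties^3 - ties) / (N * (N - 1))
  v <- n1 * n0 / 12 * ((N + 1) - tieAdj)
  if (v <= 0) return(0.5)               # all scores tied: AUC pinned at 0.5
  z <- (U - n1 * n0 / 2 - 0.5) / sqrt(v)
  pnorm(z, lower.tail = FALSE)
}

#' Fisher linear discriminant with ridge fallback
#'
#' Two-class linear discriminant: weights w = S^-1 (mu+ - mu-) with S the
#' pooled within-class covariance, offset centering the score at the class
#' midpoint, oriented so that higher scores indicate the positive class. When
#' S is singular (likely with binary covariates on small splits) a ridge
#' epsilon = 1e-6 * trace(S) / d is added to the diagonal.
#'
#' @param x Numeric matrix or data.frame (samples x features, >= 1 column).
#' @param labels Logical (or 0/1) labels; each class needs >= 2 samples.
#' @param ridge Enable the ridge fallback (default TRUE).
#' @return List: \code{weights} (named), \code{offset}; score a new matrix
#'   with [ldaScore()].
#' @export
fitLDA <- function(x, labels, ridge = TRUE) {
  x <- as.matrix(x)
  labels <- as.logical(labels)
  stopifnot(nrow(x) == length(labels))
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("each class needs at least 2 samples")
  mu1 <- colMeans(x[labels, , drop = FALSE])
  mu0 <- colMeans(x[!labels, , drop = FALSE])
  n1 <- sum(labels); n0 <- sum(!labels)
  S <- ((n1 - 1) * cov(x[labels, , drop = FALSE]) +
          (n0 - 1) * cov(x[!labels, , drop = FALSE])) / (n1 + n0 - 2)
  d <- ncol(x)
  w <- tryCatch(solve(S, mu1 - mu0), error = function(e) NULL)
  if (is.null(w)) {
    if (!ridge) stop("singular pooled covariance and ridge disabled")
    eps <- 1e-6 * sum(diag(S)) / d
    if (eps <= 0) eps <- 1e-8
    w <- solve(S + diag(eps, d), mu1 - mu0)
  }
  names(w) <- colnames(x)
  list(weights = w, offset = -sum(w * (mu1 + mu0) / 2))
}

#' Score samples with a fitted linear discriminant
#'
#' @param fit List from [fitLDA()].
#' @param x Matrix or data.frame carrying the fit's feature columns.
#' @return Numeric scores, higher = more positive-like.
#' @export
ldaScore <- function(fit, x) {
  x <- as.matrix(x)[, names(fit$weights), drop = FALSE]
  as.vector(x %*% fit$weights) + fit$offset
}

#' Outcome labels for the three clinical contrasts
#'
#' \describe{
#'   \item{recurrence}{recurrent vs non-recurrent followed >= 90 months.}
#'   \item{fast}{PSADT <= 4 months vs (non-recurrent >= 90 months, or
#'     recurrent with PSADT >= 15 months); recurrences with 4 < PSADT < 15
#'     belong to neither arm and are excluded.}
#'   \item{lethal}{recurrence within 12 months with PSADT <= 4 months vs
#'     non-recurrent >= 90 months.}
#' }
#' Contrasts are nested: lethal cases are a subset of fast cases, which are a
#' subset of recurrent cases.
#'
#' @param clinical Clinical data.frame ([readClinical()] layout).
#' @param contrast One of "recurrence", "fast", "lethal".
#' @return Logical vector aligned with \code{clinical} rows; TRUE = positive
#'   class, NA = excluded from the contrast.
#' @export
contrastLabels <- function(clinical,
                           contrast = c("recurrence", "fast", "lethal")) {
  contrast <- match.arg(contrast)
  rec <- clinical$recurrent
  elig <- clinical$eligible_nonrecurrent
  psadt <- clinical$psadt_months
  lab <- rep(NA, nrow(clinical))
  if (contrast == "recurrence") {
    lab[rec] <- TRUE
    lab[!rec & elig] <- FALSE
  } else if (contrast == "fast") {
    lab[rec & !is.na(psadt) & psadt <= 4] <- TRUE
    lab[(!rec & elig) | (rec & !is.na(psadt) & psadt >= 15)] <- FALSE
  } else {
    lab[rec & !is.na(psadt) & psadt <= 4 &
          clinical$followup_months <= 12] <- TRUE
    lab[!rec & elig] <- FALSE
  }
  lab
}

# classification + ranking metrics for one evaluation of one half
.splitMetrics <- function(scores, labels, cutoff) {
  pred <- scores >= cutoff
  sens <- mean(pred[labels]); spec <- mean(!pred[!labels])
  c(accuracy = mean(pred == labels),
    balanced_accuracy = (sens + spec) / 2,
    sensitivity = sens, specificity = spec,
    youden = sens + spec - 1,
    auc = rocAuc(scores, labels)$auc,
    roc_p = rocPvalue(scores, labels))
}

# train an LSRModel on one half: tune delta (if L), fit LDA (if >= 2
# modalities; single modality uses the raw oriented feature), fit the cutoff
.trainHalf <- function(profiles, clinical, labels, modalities, grid) {
  if ("L" %in% modalities) {
    od <- optimizeDelta(profiles[clinical$sample], labels, grid)
    lsr <- computeLSR(profiles, od$delta)
    log10d <- od$log10_delta; delta <- od$delta; curve <- od$curve
  } else {
    lsr <- NULL; log10d <- NA_real_; delta <- NA_real_
    curve <- data.frame(log10_delta = numeric(), auc = numeric())
  }
  feat <- assembleFeatures(clinical, lsr, modalities)
  if (ncol(feat) == 1L) {
    fit <- list(weights = setNames(1, colnames(feat)), offset = 0)
  } else {
    fit <- fitLDA(feat, labels)
  }
  scores <- ldaScore(fit, feat)
  ct <- fitCutoff(scores, labels)
  new("LSRModel", modalities = modalities, log10Delta = log10d,
      delta = delta, weights = fit$weights, offset = fit$offset,
      cutoff = ct$cutoff, deltaCurve = curve)
}

# score a clinical subset with a fitted LSRModel
.applyModel <- function(model, profiles, clinical) {
  lsr <- if ("L" %in% model@modalities)
    computeLSR(profiles[clinical$sample], model@delta) else NULL
  feat <- assembleFeatures(clinical, lsr, model@modalities)
  ldaScore(list(weights = model@weights, offset = model@offset), feat)
}

# align (profiles, clinical) on a contrast: drops excluded samples and, when
# "L" is used, samples lacking a profile
.contrastData <- function(profiles, clinical, contrast, modalities) {
  lab <- contrastLabels(clinical, contrast)
  keep <- !is.na(lab)
  if ("L" %in% modalities)
    keep <- keep & clinical$sample %in% sampleIDs(profiles)
  if (!any(keep)) stop("no samples usable for contrast '", contrast, "'")
  list(clinical = clinical[keep, , drop = FALSE], labels = lab[keep])
}

#' One repeat of the two-fold cross-validation
#'
#' Randomly and equally splits the contrast samples into two halves. A model
#' (large-size threshold if "L" is used, discriminant weights for >= 2
#' modalities, and the Youden decision cutoff) is trained on the first half
#' and evaluated on both halves; the roles are then swapped. The two train
#' evaluations and the two test evaluations are averaged per role (p-values
#' by geometric mean). Splits leaving a one-class half are redrawn (at most
#' 100 times, with a message).
#'
#' @param profiles A [CNVProfiles-class].
#' @param clinical Clinical data.frame.
#' @param contrast One of "recurrence", "fast", "lethal".
#' @param modalities Character subset of c("L", "N", "F", "G").
#' @param seed Integer seed for the split.
#' @param grid log10(bp) threshold grid passed to [optimizeDelta()].
#' @return List: \code{train}, \code{test} (named metric vectors:
#'   accuracy, balanced_accuracy, sensitivity, specificity, youden, auc,
#'   roc_p), \code{models} (the two fitted [LSRModel-class]s), and
#'   \code{assignment} (the two index sets).
#' @export
runSplit <- function(profiles, clinical, contrast, modalities, seed,
                     grid = seq(3.3, 6.5, by = 0.1)) {
  dat <- .contrastData(profiles, clinical, contrast, modalities)
  n <- nrow(dat$clinical)
  if (n < 4L) stop("too few samples for a two-fold split")
  set.seed(seed)
  for (attempt in seq_len(100L)) {
    perm <- sample.int(n)
    h1 <- sort(perm[seq_len(n %/% 2)]); h2 <- sort(perm[-seq_len(n %/% 2)])
    ok <- length(unique(dat$labels[h1])) == 2L &&
      length(unique(dat$labels[h2])) == 2L
    if (ok) break
    if (attempt == 100L) stop("could not draw a split with both classes")
    message("redrawing split ", attempt, ": a half had a single class")
  }
  evalRoles <- function(trainIdx, testIdx) {
    model <- .trainHalf(profiles, dat$clinical[trainIdx, , drop = FALSE],
                        dat$labels[trainIdx], modalities, grid)
    list(model = model,
         train = .splitMetrics(
           .applyModel(model, profiles, dat$clinical[trainIdx, , drop = FALSE]),
           dat$labels[trainIdx], model@cutoff),
         test = .splitMetrics(
           .applyModel(model, profiles, dat$clinical[testIdx, , drop = FALSE]),
           dat$labels[testIdx], model@cutoff))
  }
  a <- evalRoles(h1, h2)
  b <- evalRoles(h2, h1)
  mergeRole <- function(m1, m2) {
    out <- (m1 + m2) / 2
    out["roc_p"] <- geometricMeanP(c(m1["roc_p"], m2["roc_p"]))
    out
  }
  list(train = mergeRole(a$train, b$train),
       test = mergeRole(a$test, b$test),
       models = list(a$model, b$model),
       assignment = list(h1 = h1, h2 = h2))
}

#' Trimmed repeated two-fold cross-validation
#'
#' Repeats [runSplit()] \code{nRepeats} times (default 14), ranks the repeats
#' by the sum of their train and test AUCs, removes the \code{trim} highest
#' and \code{trim} lowest (default 2 + 2, guarding against accidentally
#' extreme train/test assignments), and averages the retained repeats per
#' metric (p-values by geometric mean). The representative repeat is the
#' retained one whose metric vector lies closest (Euclidean, over the six
#' non-p metrics of both roles) to the trimmed average.
#'
#' @inheritParams runSplit
#' @param nRepeats Number of repeats (default 14).
#' @param trim Repeats to drop from each extreme (default 2).
#' @param seed Master seed; per-repeat seeds are derived from it.
#' @return A [CVSummary-class].
#' @export
trimmedCV <- function(profiles, clinical, contrast, modalities,
                      nRepeats = 14L, trim = 2L, seed = 1L,
                      grid = seq(3.3, 6.5, by = 0.1)) {
  nRepeats <- as.integer(nRepeats); trim <- as.integer(trim)
  if (nRepeats <= 2L * trim) stop("nRepeats must exceed 2 * trim")
  set.seed(seed)
  repSeeds <- sample.int(.Machine$integer.max, nRepeats)
  runs <- lapply(repSeeds, function(s)
    runSplit(profiles, clinical, contrast, modalities, s, grid))
  splits <- do.call(rbind, lapply(seq_along(runs), function(i) {
    tr <- runs[[i]]$train; te <- runs[[i]]$test
    names(tr) <- paste0("train_", names(tr))
    names(te) <- paste0("test_", names(te))
    data.frame(repeat_id = i, seed = repSeeds[i], t(c(tr, te)))
  }))
  aucSum <- splits$train_auc + splits$test_auc
  ord <- order(aucSum)
  retained <- if (trim > 0L)
    sort(ord[(trim + 1L):(nRepeats - trim)]) else seq_len(nRepeats)
  avgRole <- function(role) {
    m <- vapply(runs[retained], `[[`, numeric(7), role)
    out <- rowMeans(m)
    out["roc_p"] <- geometricMeanP(m["roc_p", ])
    out
  }
  trainAvg <- avgRole("train"); testAvg <- avgRole("test")
  keep <- setdiff(names(trainAvg), "roc_p")
  target <- c(trainAvg[keep], testAvg[keep])
  dist <- vapply(runs[retained], function(r)
    sqrt(sum((c(r$train[keep], r$test[keep]) - target)^2)), numeric(1))
  new("CVSummary", contrast = contrast, modalities = modalities,
      train = trainAvg, test = testAvg, splits = splits,
      retained = as.integer(retained),
      representative = as.integer(retained[which.min(dist)]),
      nRepeats = nRepeats, trim = trim)
}

#' Geometric mean of p-values
#'
#' exp(mean(log p)); the aggregation used to summarize a p-value over the
#' retained cross-validation repeats.
#'
#' @param p Numeric p-values in (0, 1].
#' @return Scalar in (0, 1].
#' @export
geometricMeanP <- function(p) {
  if (any(is.na(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  exp(mean(log(p)))
}
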