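# Independent oracles used across the suite. Each is deliberately the dumbest
# correct computation (enumeration / quadrature / hand arithmetic), kept
# separate from the package's own code paths.

# build a segment GRanges directly (bypasses readSegments)
makeSegments <- function(sample, chrom, start, end, markers, state, pvalue) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end),
                         sample = sample, markers = as.integer(markers),
                         state = factor(state, levels = c("loss", "gain")),
                         pvalue = pvalue)
}

# AUC by exhaustive (+,-) pair counting
pairCountAUC <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# best Youden over every distinct threshold (values and midpoints)
bruteYouden <- function(scores, labels) {
  v <- sort(unique(scores))
  cand <- sort(unique(c(v, if (length(v) > 1) (v[-1] + v[-length(v)]) / 2)))
  best <- -Inf
  for (ct in cand) {
    pred <- scores >= ct
    j <- mean(pred[labels]) + mean(!pred[!labels]) - 1
    if (j > best) best <- j
  }
  best
}

# two-sided Fisher p by full hypergeometric enumeration of one margin
fisherEnum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  pr <- dhyper(x, m, n, k)
  sum(pr[pr <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# survival function of |X - Y| for independent chi-squared(1) X, Y.
# X - Y = 2 * Z1 * Z2 with Z iid N(0,1), whose density is K0(|w|) / pi,
# so P(|X - Y| >= u) = (2 / pi) * integral_{u/2}^Inf K0(t) dt.
absChisqDiffSF <- function(u) {
  if (u <= 0) return(1)
  2 / pi * integrate(function(t) besselK(t, 0), u / 2, Inf,
                     rel.tol = 1e-10)$value
}

# quantile of |X - Y| via root finding on the quadrature CDF
absChisqDiffQ <- function(p) {
  vapply(p, function(pp)
    uniroot(function(u) (1 - absChisqDiffSF(u)) - pp,
            c(1e-12, 60), tol = 1e-9)$root, numeric(1))
}

# two-group log-rank chi-squared by the textbook observed - expected /
# variance tables, one row per distinct event time
logrankByHand <- function(time, event, group) {
  g <- as.integer(as.factor(group))
  ts <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (t in ts) {
    atRisk <- time >= t
    n <- sum(atRisk); n1 <- sum(atRisk & g == 1)
    d <- sum(event & time == t); d1 <- sum(event & time == t & g == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1)
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# --- planted-signal cohort: closed-model simulators used as the reference
# for threshold recovery and combined-model discriminability. These draw
# straight from the generative distributions (beta mixture weights, negative
# binomial counts, binomial large-fragment tallies, beta nomogram, logistic
# fusion gate) without touching the package's cohort generator.

plantedCohortSpec <- function(seed) cohortSpec(
  nNonrecurrent = 150L, nRecurrentFast = 75L, nRecurrentSlow = 75L,
  mixtureProb = 0.35, baseMixtureProb = 0.05, mixtureConcentration = 10,
  sizeFoldRecurrent = 1.8, sizeLog10SD = 0.3, seed = seed)

plantedGrid <- seq(3.5, 6.3, by = 0.4)

plantedMinLog10 <- log10(2000)     # fragment sizes are drawn above 2 kb

.plantedTruncMean <- function(m, s, a = plantedMinLog10) {
  c_ <- log(10)
  10^m * exp((c_ * s)^2 / 2) * pnorm((m + c_ * s^2 - a) / s) /
    pnorm((m - a) / s)
}

.plantedOffset <- function(spec) {
  fold <- spec@sizeFoldRecurrent
  mu0 <- spec@baseMixtureProb; mur <- spec@mixtureProb
  MB <- .plantedTruncMean(spec@sizeLog10Mean, spec@sizeLog10SD)
  MI <- MB * (fold * (1 - mu0) - (1 - mur)) / (mur - fold * mu0)
  off <- log10(MI / MB)
  for (i in 1:6)
    off <- off + log10(MI / .plantedTruncMean(spec@sizeLog10Mean + off,
                                              spec@sizeLog10SD))
  off
}

# tail probability of a 2 kb-truncated log-normal component
.plantedTail <- function(g, m, s, a = plantedMinLog10) {
  if (g <= a) return(1)
  (1 - pnorm((g - m) / s)) / (1 - pnorm((a - m) / s))
}

# one arm of per-patient LSR draws at log10 threshold g
plantedLSRDraw <- function(n, mu, spec, g) {
  pis <- rbeta(n, spec@mixtureConcentration * mu,
               spec@mixtureConcentration * (1 - mu))
  ns <- pmax(1, rnbinom(n, size = spec@dispersion, mu = spec@meanFragments))
  p0 <- .plantedTail(g, spec@sizeLog10Mean, spec@sizeLog10SD)
  pI <- .plantedTail(g, spec@sizeLog10Mean + .plantedOffset(spec),
                     spec@sizeLog10SD)
  rbinom(n, ns, (1 - pis) * p0 + pis * pI) / ns
}

rankAUC <- function(sPos, sNeg) {
  r <- rank(c(sPos, sNeg))
  (sum(r[seq_along(sPos)]) - length(sPos) * (length(sPos) + 1) / 2) /
    (length(sPos) * length(sNeg))
}

# population AUC(delta) curve of the planted model
plantedOracleCurve <- function(spec, nPerArm = 4000) {
  vapply(plantedGrid, function(g)
    rankAUC(plantedLSRDraw(nPerArm, spec@mixtureProb, spec, g),
            plantedLSRDraw(nPerArm, spec@baseMixtureProb, spec, g)),
    numeric(1))
}

# one arm of (L, N, F) feature draws at log10 threshold g
plantedFeatureDraw <- function(n, z, mu, spec, g) {
  L <- plantedLSRDraw(n, mu, spec, g)
  m <- pmin(0.98, pmax(0.02, 0.80 - 0.12 * z))
  N <- 1 - rbeta(n, m * 8, (1 - m) * 8)
  F_ <- as.numeric(runif(n) < 1 / (1 + exp(0.8 - 0.9 * z)))
  cbind(L = L, N = N, F = F_)
}

# population discriminability of the pooled-covariance linear combination of
# L + N + F, estimated on an independent draw (the recurrent arm mixes the
# fast and slow covariate shifts half and half, as in the cohort design)
plantedCombinedAUC <- function(spec, g, nPerArm = 4000) {
  draw <- function() {
    xPos <- rbind(
      plantedFeatureDraw(nPerArm %/% 2, 1.3, spec@mixtureProb, spec, g),
      plantedFeatureDraw(nPerArm - nPerArm %/% 2, 1.0, spec@mixtureProb,
                         spec, g))
    xNeg <- plantedFeatureDraw(nPerArm, 0, spec@baseMixtureProb, spec, g)
    list(pos = xPos, neg = xNeg)
  }
  tr <- draw(); te <- draw()
  S <- (cov(tr$pos) + cov(tr$neg)) / 2
  w <- solve(S, colMeans(tr$pos) - colMeans(tr$neg))
  rankAUC(te$pos %*% w, te$neg %*% w)
}

# exact two-sample KS p-value by enumerating every group assignment
ksEnumP <- function(x, y) {
  all <- c(x, y); m <- length(x); n <- length(y)
  dStat <- function(a, b) {
    grid <- sort(unique(c(a, b)))
    max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
  }
  obs <- dStat(x, y)
  idx <- combn(m + n, m)
  ds <- apply(idx, 2, function(i) dStat(all[i], all[-i]))
  mean(ds >= obs - 1e-12)
}
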