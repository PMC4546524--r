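test_that("AUC equals exhaustive pair counting, with ties", {
  s <- c(0.1, 0.4, 0.4, 0.7, 0.8, 0.2)
  l <- c(FALSE, FALSE, TRUE, TRUE, TRUE, FALSE)
  expect_equal(rocAuc(s, l)$auc, pairCountAUC(s, l))
  expect_equal(rocAuc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE))$auc, 1)
  expect_equal(rocAuc(rep(2, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  set.seed(5)
  for (rep in 1:20) {
    n <- sample(5:15, 1)
    s <- sample(round(runif(n), 1))          # coarse => ties
    l <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    expect_equal(rocAuc(s, l)$auc, pairCountAUC(s, l))
  }
  expect_error(rocAuc(1:3, rep(TRUE, 3)), "both classes")
})

test_that("AUC and best Youden agree with the pROC reference", {
  set.seed(98)
  s <- rnorm(50); l <- c(TRUE, FALSE, runif(48) < 0.45)
  r <- pROC::roc(l, s, quiet = TRUE, direction = "<")
  expect_equal(rocAuc(s, l)$auc, as.numeric(pROC::auc(r)))
  best <- pROC::coords(r, "best", best.method = "youden", transpose = FALSE)
  expect_equal(fitCutoff(s, l)$youden,
               max(best$sensitivity + best$specificity - 1))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(6)
  s <- rnorm(30); l <- runif(30) < 0.4; l[1:2] <- c(TRUE, FALSE)
  a <- rocAuc(s, l)$auc
  expect_equal(rocAuc(exp(s), l)$auc, a)
  expect_equal(rocAuc(rank(s), l)$auc, a)
})

test_that("ROC curve runs from (0,0) to (1,1) and is monotone", {
  set.seed(7)
  p <- rocAuc(rnorm(40), runif(40) < 0.5)$points
  expect_equal(c(p$fpr[1], p$tpr[1]), c(0, 0))
  expect_equal(c(tail(p$fpr, 1), tail(p$tpr, 1)), c(1, 1))
  expect_true(all(diff(p$fpr) >= 0) && all(diff(p$tpr) >= 0))
})

test_that("normal-approximation ROC p-value behaves across regimes", {
  expect_gte(rocPvalue(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(8)
  s <- c(rnorm(100), rnorm(100, 3)); l <- rep(c(FALSE, TRUE), each = 100)
  expect_lt(rocPvalue(s, l), 1e-6)
  # near-null scores give a large p
  s0 <- rnorm(60); l0 <- rep(c(TRUE, FALSE), 30)
  expect_gt(rocPvalue(sample(s0), l0), 0.01)
})

test_that("exact permutation p matches an external exact Mann-Whitney", {
  set.seed(12)
  for (rep in 1:5) {
    x <- rnorm(5, 1); y <- rnorm(6)          # no ties a.s.
    p <- rocPvalue(c(x, y), rep(c(TRUE, FALSE), c(5, 6)), method = "exact")
    pw <- wilcox.test(x, y, alternative = "greater", exact = TRUE)$p.value
    expect_equal(p, pw, tolerance = 1e-10)
  }
})

test_that("LDA recovers the closed-form direction on isotropic clouds", {
  set.seed(15)
  mu <- c(2, -1, 0.5)
  x <- rbind(sweep(matrix(rnorm(3000), ncol = 3), 2, mu, "+"),
             matrix(rnorm(3000), ncol = 3))
  colnames(x) <- c("a", "b", "c")
  l <- rep(c(TRUE, FALSE), each = 1000)
  fit <- fitLDA(x, l)
  dir <- fit$weights / sqrt(sum(fit$weights^2))
  expect_equal(unname(dir), mu / sqrt(sum(mu^2)), tolerance = 0.1)
  # independent route: MASS::lda must rank samples identically
  ml <- MASS::lda(x, grouping = l)
  sMine <- ldaScore(fit, x)
  sMass <- as.vector(x %*% ml$scaling)
  if (cor(sMine, sMass) < 0) sMass <- -sMass
  expect_equal(order(sMine), order(sMass))
})

test_that("ridge fallback tames duplicated features without reranking", {
  set.seed(16)
  x1 <- matrix(c(rnorm(40, rep(c(1, 0), each = 20))), ncol = 1,
               dimnames = list(NULL, "a"))
  l <- rep(c(TRUE, FALSE), each = 20)
  x2 <- cbind(x1, a2 = x1[, 1])              # exactly collinear
  f2 <- fitLDA(x2, l)
  expect_true(all(is.finite(f2$weights)))
  expect_equal(order(ldaScore(f2, x2)), order(x1[, 1]))
  expect_error(fitLDA(x2, l, ridge = FALSE), "singular")
  # single feature: scorer is monotone in the raw feature
  f1 <- fitLDA(x1, l)
  expect_equal(order(ldaScore(f1, x1)), order(x1[, 1]))
})

test_that("contrast arms are nested and exclusions respected", {
  co <- generateCohort(cohortSpec(seed = 19L))
  cl <- co$clinical
  labR <- contrastLabels(cl, "recurrence")
  labF <- contrastLabels(cl, "fast")
  labL <- contrastLabels(cl, "lethal")
  expect_true(all(which(labF %in% TRUE) %in% which(labR %in% TRUE)))
  expect_true(all(which(labL %in% TRUE) %in% which(labF %in% TRUE)))
  mid <- cl$recurrent & !is.na(cl$psadt_months) &
    cl$psadt_months > 4 & cl$psadt_months < 15
  expect_true(all(is.na(labF[mid])))
  expect_true(all(labL[!cl$recurrent & cl$eligible_nonrecurrent] %in% FALSE))
})

test_that("split metrics are internally consistent and seed-deterministic", {
  co <- generateCohort(cohortSpec(seed = 23L))
  pr <- buildProfiles(filterSegments(co$segments))
  r1 <- runSplit(pr, co$clinical, "recurrence", c("L", "N"), seed = 4L)
  r2 <- runSplit(pr, co$clinical, "recurrence", c("L", "N"), seed = 4L)
  expect_identical(r1$train, r2$train)
  expect_identical(r1$test, r2$test)
  for (m in list(r1$train, r1$test)) {
    expect_equal(unname(m["youden"]),
                 unname(m["sensitivity"] + m["specificity"] - 1),
                 tolerance = 1e-12)
    expect_true(all(m[c("sensitivity", "specificity")] >= 0 &
                      m[c("sensitivity", "specificity")] <= 1))
    expect_true(m["auc"] >= 0 && m["auc"] <= 1)
  }
})

test_that("trimming retains the sorted middle repeats and averages them", {
  co <- generateCohort(cohortSpec(nNonrecurrent = 20L, nRecurrentFast = 12L,
                                  nRecurrentSlow = 12L, seed = 29L))
  pr <- buildProfiles(filterSegments(co$segments))
  cv <- trimmedCV(pr, co$clinical, "recurrence", "N",
                  nRepeats = 14L, trim = 2L, seed = 6L)
  expect_length(cv@retained, 10L)            # 14 - 2*2
  aucSum <- cv@splits$train_auc + cv@splits$test_auc
  expect_setequal(cv@retained, order(aucSum)[3:12])  # explicit sort oracle
  expect_equal(unname(cv@test["auc"]),
               mean(cv@splits$test_auc[cv@retained]))
  expect_equal(unname(cv@test["roc_p"]),
               geometricMeanP(cv@splits$test_roc_p[cv@retained]))
  expect_true(cv@representative %in% cv@retained)
})

test_that("with trim = 0 the summary is the plain mean of all repeats", {
  co <- generateCohort(cohortSpec(nNonrecurrent = 16L, nRecurrentFast = 8L,
                                  nRecurrentSlow = 8L, seed = 33L))
  pr <- buildProfiles(filterSegments(co$segments))
  cv <- trimmedCV(pr, co$clinical, "recurrence", "N",
                  nRepeats = 3L, trim = 0L, seed = 2L)
  expect_equal(cv@retained, 1:3)
  expect_equal(unname(cv@train["accuracy"]), mean(cv@splits$train_accuracy))
  expect_error(trimmedCV(pr, co$clinical, "recurrence", "N",
                         nRepeats = 4L, trim = 2L, seed = 2L), "exceed")
})

test_that("geometric mean of p-values follows the log-mean identity", {
  expect_equal(geometricMeanP(c(0.01, 0.01)), 0.01)
  expect_equal(geometricMeanP(c(1, 1, 1)), 1)
  expect_equal(geometricMeanP(c(0.1, 0.001)), 0.01)
  expect_error(geometricMeanP(c(0.5, 0)), "0, 1")
})
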