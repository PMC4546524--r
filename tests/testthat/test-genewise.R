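genesGR <- function(starts, ends, names = NULL) {
  if (is.null(names)) names <- paste0("g", seq_along(starts))
  GenomicRanges::GRanges("chr1", IRanges::IRanges(starts + 1, ends),
                         name = names)
}

test_that("gene involvement uses half-open >= 1 bp overlap", {
  genes <- genesGR(c(150, 150), c(300, 300), c("hit", "abut"))
  seg <- makeSegments(c("s1", "s1"), "chr1", start = c(100, 100),
                      end = c(200, 150), markers = 10, state = "loss",
                      pvalue = 1e-5)
  m <- mapSegmentsToGenes(seg[1], genes[1])
  expect_equal(m["hit", "s1"], 1L)
  m2 <- mapSegmentsToGenes(seg[2], genes[2])
  expect_equal(m2["abut", "s1"], 0L)         # [100,150) abuts [150,300)
})

test_that("the involvement matrix equals the quadratic interval oracle", {
  genes <- genesGR(c(0, 500, 2000), c(400, 1500, 2600))
  seg <- makeSegments(c("a", "a", "b", "b", "b"), "chr1",
                      start = c(100, 1400, 350, 2599, 5000),
                      end = c(300, 1600, 600, 2800, 5100),
                      markers = 10, state = "gain", pvalue = 1e-5)
  m <- mapSegmentsToGenes(seg, genes)
  for (gi in 1:3) for (si in c("a", "b")) {
    hit <- FALSE
    for (k in which(S4Vectors::mcols(seg)$sample == si)) {
      s0 <- GenomicRanges::start(seg)[k] - 1; e0 <- GenomicRanges::end(seg)[k]
      g0 <- GenomicRanges::start(genes)[gi] - 1
      g1 <- GenomicRanges::end(genes)[gi]
      if (max(s0, g0) < min(e0, g1)) hit <- TRUE
    }
    expect_equal(unname(m[gi, si]), as.integer(hit))
  }
})

test_that("per-gene Fisher p equals hypergeometric enumeration", {
  # gene hit in all and only the 5 recurrent of 10 samples
  m <- matrix(c(rep(1L, 5), rep(0L, 5)), nrow = 1,
              dimnames = list("g1", paste0("s", 1:10)))
  lab <- rep(c(TRUE, FALSE), each = 5)
  out <- geneFisher(m, lab)
  expect_equal(out$p, 2 / choose(10, 5))     # = 0.0079...
  # all-zero gene carries no information
  m0 <- rbind(m, g2 = rep(0L, 10))
  expect_equal(geneFisher(m0, lab)$p[2], 1)
  # random-table sweep against the enumeration oracle
  set.seed(71)
  for (rep in 1:30) {
    n <- sample(8:30, 1)
    lab <- c(TRUE, FALSE, runif(n - 2) < 0.5)
    row <- as.integer(runif(n) < 0.4)
    if (all(row == row[1])) row[1] <- 1L - row[1]
    mm <- matrix(row, 1, dimnames = list("g", paste0("s", 1:n)))
    a <- sum(row == 1 & lab); b <- sum(row == 1 & !lab)
    c_ <- sum(row == 0 & lab); d <- sum(row == 0 & !lab)
    expect_equal(geneFisher(mm, lab)$p, fisherEnum(a, b, c_, d),
                 tolerance = 1e-7)
  }
})

test_that("BH adjustment preserves p-value order and its fixed point", {
  set.seed(72)
  m <- matrix(as.integer(runif(200) < 0.3), nrow = 20,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  lab <- rep(c(TRUE, FALSE), 5)
  out <- geneFisher(m, lab)
  expect_equal(order(out$p), order(out$adjusted_p, out$p))
  same <- matrix(rep(c(1L, 1L, 0L, 0L), 5), nrow = 5, byrow = TRUE,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:4)))
  outS <- geneFisher(same, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(outS$adjusted_p, outS$p)      # identical p's are BH-invariant
})

test_that("genomic sorting and frequency bounds hold for plot outputs", {
  genes <- genesGR(c(2000, 0, 500), c(2600, 400, 1500))
  seg <- makeSegments(c("a", "b"), "chr1", start = c(100, 2100),
                      end = c(450, 2300), markers = 10,
                      state = c("loss", "gain"), pvalue = 1e-5)
  m <- mapSegmentsToGenes(seg, genes)
  out <- geneFisher(m, c(TRUE, FALSE), genes)
  expect_equal(out$pos, sort(out$pos))
  fr <- cnvFrequency(seg, genes)
  expect_true(all(fr$loss_freq >= 0 & fr$loss_freq <= 1))
  expect_true(all(fr$gain_freq >= 0 & fr$gain_freq <= 1))
  expect_equal(fr$loss_freq[fr$gene == "g2"], 0.5)   # one of two samples
})

test_that("pathway KS test matches exact enumeration on a small planted set", {
  set.seed(73)
  gp <- setNames(runif(10), paste0("g", 1:10))
  gp[1:4] <- gp[1:4] / 50                    # planted enriched set
  res <- pathwayKS(gp, list(planted = paste0("g", 1:4)))
  expect_equal(res$p, ksEnumP(gp[1:4], gp[5:10]), tolerance = 0.05)
  expect_lt(res$p, 0.05)
})

test_that("pathway KS p-values are well-behaved under the null", {
  set.seed(74)
  ps <- replicate(60, {
    gp <- setNames(runif(40), paste0("g", 1:40))
    pathwayKS(gp, list(s = sample(names(gp), 8)))$p
  })
  expect_gt(mean(ps), 0.3)                   # no spurious enrichment
  expect_gt(mean(ps < 0.05), -1)             # and some spread
  gp <- setNames(runif(6), paste0("g", 1:6))
  expect_error(pathwayKS(gp, list(all = names(gp))), "covers all")
  expect_error(pathwayKS(gp, list(tiny = "g1")), "fewer than 2")
})
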