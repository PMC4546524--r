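segHeader <- "sample\tchrom\tstart\tend\tmarkers\tstate\tpvalue"

writeSegFile <- function(rows) {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c(segHeader, rows), tf)
  tf
}

test_that("well-formed tables parse row for row with normalized coordinates", {
  tf <- writeSegFile(c("s1\tchr1\t100\t5100\t25\tloss\t1e-05",
                       "s1\tchr2\t0\t2000\t12\tgain\t0.0005",
                       "s2\tchr1\t999\t1000\t10\tloss\t0.5"))
  gr <- readSegments(tf)
  expect_length(gr, 3L)
  expect_equal(GenomicRanges::width(gr), c(5000, 2000, 1))
  expect_equal(S4Vectors::mcols(gr)$sample, c("s1", "s1", "s2"))
  expect_equal(as.character(S4Vectors::mcols(gr)$state),
               c("loss", "gain", "loss"))
})

test_that("1-based inclusive input is normalized: (101, 200) spans 100 bp", {
  tf <- writeSegFile("s1\tchr1\t101\t200\t10\tgain\t1e-4")
  gr <- readSegments(tf, dialect = "partek")
  expect_equal(GenomicRanges::width(gr), 100)
  out <- tempfile()
  writeSegments(gr, out)
  fields <- strsplit(readLines(out)[2], "\t")[[1]]
  expect_equal(as.numeric(fields[3:4]), c(100, 200))  # canonical half-open
})

test_that("invalid rows are rejected with row-indexed diagnostics", {
  expect_error(readSegments(writeSegFile("s1\tchr1\t500\t500\t10\tloss\t0.1")),
               "row.*1")
  expect_error(readSegments(writeSegFile(
    c("s1\tchr1\t100\t200\t10\tloss\t0.1",
      "s1\tchr1\tabc\t200\t10\tloss\t0.1"))), "coordinate.*2")
  expect_error(readSegments(writeSegFile("s1\tchr1\t1\t9\t10\tweird\t0.1")),
               "state")
  expect_error(readSegments(writeSegFile("s1\tchr1\t1\t9\t10\tloss\t1.5")),
               "p-value")
  tf <- tempfile(); writeLines(c("sample\tchrom\tstart", "s1\tchr1\t1"), tf)
  expect_error(readSegments(tf), "required column")
})

test_that("filter keeps exactly the size>=2kb, markers>=10, p<0.001 calls", {
  gr <- makeSegments("s", "chr1",
                     start = c(0, 0, 0, 0),
                     end = c(1999, 2000, 5000, 5000),
                     markers = c(10, 10, 9, 10),
                     state = "loss",
                     pvalue = c(1e-4, 1e-4, 1e-4, 0.001))
  kept <- filterSegments(gr)
  expect_equal(GenomicRanges::width(kept), 2000)  # only the boundary-pass row
})

test_that("filter agrees with the row-by-row predicate and is idempotent", {
  set.seed(42)
  n <- 10
  gr <- makeSegments(sample(c("a", "b"), n, TRUE), "chr3",
                     start = 1:n * 10L,
                     end = 1:n * 10L + sample(c(1500L, 2500L, 40000L), n, TRUE),
                     markers = sample(5:20, n, TRUE), state = "gain",
                     pvalue = sample(c(1e-5, 5e-4, 0.01), n, TRUE))
  keep <- logical(n)
  for (i in seq_len(n))
    keep[i] <- GenomicRanges::width(gr)[i] >= 2000 &&
      S4Vectors::mcols(gr)$markers[i] >= 10 &&
      S4Vectors::mcols(gr)$pvalue[i] < 0.001
  f1 <- filterSegments(gr)
  expect_identical(f1, gr[keep])                # brute-force predicate
  expect_identical(filterSegments(f1), f1)      # idempotent
  perm <- sample(n)
  fp <- filterSegments(gr[perm])                # commutes with permutation
  expect_setequal(paste(GenomicRanges::start(fp), S4Vectors::mcols(fp)$sample),
                  paste(GenomicRanges::start(f1), S4Vectors::mcols(f1)$sample))
})

test_that("profiles partition the filtered segments by sample", {
  gr <- makeSegments(c("a", "b", "a", "b", "a"), "chr1",
                     start = c(0, 10, 100, 110, 200) * 1000L,
                     end = c(5, 14, 103, 119, 208) * 1000L,
                     markers = 10, state = "loss", pvalue = 1e-5)
  pr <- buildProfiles(gr)
  expect_equal(sort(sampleIDs(pr)), c("a", "b"))
  expect_equal(unname(nSegments(pr)[c("a", "b")]), c(3L, 2L))
  expect_equal(sort(profileSizes(pr)$b), c(4000, 9000))
  expect_equal(sum(nSegments(pr)), length(gr))
  expect_length(buildProfiles(gr[0]), 0L)
  expect_equal(unname(meanSize(pr)["a"]), mean(c(5000, 3000, 8000)))
})

test_that("canonical tables round-trip byte-identically", {
  co <- generateCohort(cohortSpec(nNonrecurrent = 3L, nRecurrentFast = 3L,
                                  nRecurrentSlow = 2L, seed = 5L))
  f1 <- tempfile(); f2 <- tempfile()
  writeSegments(co$segments, f1)
  writeSegments(readSegments(f1), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("clinical records are validated, flagged but never dropped", {
  tf <- tempfile()
  writeLines(c("sample,recurrent,followup_months,psadt_months,gleason,nomogram_prob,fusion_count",
               "p1,TRUE,24,3.5,7,0.62,2",
               "p2,FALSE,80,NA,6,0.9,0",
               "p3,FALSE,95,NA,8,0.85,1"), tf)
  cl <- readClinical(tf)
  expect_equal(nrow(cl), 3L)
  expect_true(cl$recurrent[1] && cl$psadt_months[1] == 3.5)
  expect_false(cl$eligible_nonrecurrent[2])   # 80 months < 90: flagged
  expect_true(cl$eligible_nonrecurrent[3])

  bad <- tempfile()
  writeLines(c("sample,recurrent,followup_months,psadt_months,gleason,nomogram_prob,fusion_count",
               "p1,FALSE,95,4.0,7,0.6,0"), bad)
  expect_error(readClinical(bad), "PSADT on a non-recurrent")
  writeLines(c("sample,recurrent,followup_months,psadt_months,gleason,nomogram_prob,fusion_count",
               "p1,FALSE,95,NA,7,1.2,0"), bad)
  expect_error(readClinical(bad), "nomogram")
})
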