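si <- Seqinfo(c("chr1", "chr2"), c(100000, 100000))

writeTmpBed <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

test_that("readBed handles well-formed, empty and commented input", {
  expect_length(readBed(writeTmpBed(character(0)), si), 0L)
  f <- writeTmpBed(c("track name=x", "chr1\t100\t200", "chr2\t0\t50",
                     "chr1\t10\t40\tpk\t7.5\t+"))
  ps <- readBed(f, si)
  expect_s4_class(ps, "PeakSet")
  expect_length(ps, 3L)
  # sorted by (chrom, start); BED 0-based half-open -> 1-based closed
  expect_equal(start(ps), c(11L, 101L, 1L))
  expect_equal(end(ps), c(40L, 200L, 50L))
  expect_equal(ps$score, c(7.5, NA, NA))
})

test_that("readBed rejects malformed lines with the line number", {
  expect_error(readBed(writeTmpBed("chr1\t500\t400"), si), "line 1.*start >= end")
  expect_error(readBed(writeTmpBed(c("chr1\t1\t2", "chr1\tx\t40")), si),
               "line 2.*non-integer")
  expect_error(readBed(writeTmpBed("chr9\t1\t2"), si),
               "line 1.*unknown chromosome")
  expect_error(readBed(writeTmpBed("chr1\t0\t200001"), si),
               "beyond chromosome length")
})

test_that("writeBed/readBed round-trips coordinates and scores exactly", {
  expect_equal(length(readLines(writeBed(
    PeakSet(GRanges(seqinfo = si), "empty"), tempfile()))), 0L)
  gr <- GRanges("chr1", IRanges(c(11, 501), c(40, 900)), seqinfo = si)
  gr$score <- c(1.25, 33.5)
  ps <- PeakSet(gr, label = "rt")
  f <- tempfile(fileext = ".bed")
  writeBed(ps, f)
  back <- readBed(f, si)
  expect_equal(start(back), start(ps))
  expect_equal(end(back), end(ps))
  expect_equal(back$score, ps$score)
})

test_that("interval overlap uses half-open >=1 bp semantics and is symmetric", {
  g <- function(ch, s, e) GRanges(ch, IRanges(s + 1, e))  # BED-style args
  expect_false(intervalsOverlap(g("chr1", 0, 10), g("chr1", 10, 20)))
  expect_true(intervalsOverlap(g("chr1", 0, 10), g("chr1", 9, 20)))
  expect_false(intervalsOverlap(g("chr1", 0, 10), g("chr2", 0, 10)))
  set.seed(11)
  for (i in 1:50) {
    a <- randomIntervals(1, 1000)
    b <- randomIntervals(1, 1000)
    expect_identical(intervalsOverlap(a, b), intervalsOverlap(b, a))
  }
})

test_that("mergePeaks merges book-ends at gap 0 and matches the bitmap oracle", {
  g <- GRanges("chrT", IRanges(c(1, 6), c(10, 20)), seqinfo = toySeqinfo())
  expect_equal(grToDf(mergePeaks(g)), data.frame(start = 1L, end = 20L))
  bk <- GRanges("chrT", IRanges(c(1, 11), c(10, 20)), seqinfo = toySeqinfo())
  expect_equal(grToDf(mergePeaks(bk)), data.frame(start = 1L, end = 20L))
  expect_error(mergePeaks(g, gap = -1), "non-negative")
  set.seed(42)
  for (i in 1:20) {
    gr <- randomIntervals(100, 10000)
    gap <- sample(c(0L, 3L, 25L), 1L)
    expect_equal(grToDf(mergePeaks(gr, gap = gap)),
                 bitmapMerge(gr, 10000L, gap = gap),
                 ignore_attr = TRUE)
  }
})

test_that("mergePeaks is idempotent and never exceeds raw base totals", {
  set.seed(7)
  for (i in 1:10) {
    gr <- randomIntervals(80, 8000)
    m1 <- mergePeaks(gr)
    expect_identical(grToDf(mergePeaks(m1)), grToDf(m1))
    expect_lte(coveredBases(m1), sum(width(gr)))
  }
  # equality iff pairwise disjoint and non-book-ended
  disj <- GRanges("chrT", IRanges(c(1, 20, 40), c(10, 30, 45)),
                  seqinfo = toySeqinfo())
  expect_equal(coveredBases(mergePeaks(disj)), sum(width(disj)))
})

test_that("overlapMembership equals the all-pairs oracle", {
  q <- GRanges("chrT", IRanges(1, 10), seqinfo = toySeqinfo())
  far <- GRanges("chrT", IRanges(500, 600), seqinfo = toySeqinfo())
  expect_false(any(overlapMembership(q, list(a = far))))
  expect_true(all(overlapMembership(q, list(a = q))))
  set.seed(99)
  for (i in 1:10) {
    query <- randomIntervals(200, 10000)
    subs <- list(a = randomIntervals(200, 10000),
                 b = randomIntervals(50, 10000))
    m <- overlapMembership(query, subs)
    expect_identical(unname(m[, "a"]), pairwiseAnyOverlap(query, subs$a))
    expect_identical(unname(m[, "b"]), pairwiseAnyOverlap(query, subs$b))
  }
})

test_that("PeakSet validity enforces sortedness, bounds and known chroms", {
  expect_error(new("PeakSet",
                   GRanges("chr1", IRanges(c(50, 10), c(60, 20)), seqinfo = si),
                   label = "bad"), "sorted")
  expect_error(suppressWarnings(
    PeakSet(GRanges("chr1", IRanges(1, 2e5 + 10), seqinfo = si))),
    "exceeds|out-of-bound")
})
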