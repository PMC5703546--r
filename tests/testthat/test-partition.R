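siP <- Seqinfo("chr1", 100000)

writeGeneTable <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# BED-convention columns: gene_id chrom strand txStart txEnd exonStarts exonEnds
twoExonPlus <- "gA\tchr1\t+\t10000\t20000\t10000,19000\t11000,20000"
twoExonMinus <- "gB\tchr1\t-\t10000\t20000\t10000,19000\t11000,20000"

test_that("readAnnotation builds strand-aware gene models", {
  ann <- readAnnotation(writeGeneTable(twoExonPlus), siP)
  expect_identical(geneIds(ann), "gA")
  expect_identical(unname(tss(ann)), 10001L)
  expect_identical(unname(tes(ann)), 20000L)
  annM <- readAnnotation(writeGeneTable(twoExonMinus), siP)
  expect_identical(unname(tss(annM)), 20000L)
  expect_identical(unname(tes(annM)), 10001L)
  expect_warning(empty <- readAnnotation(writeGeneTable(character(0)), siP),
                 "empty")
  expect_length(empty, 0L)
  expect_error(readAnnotation(writeGeneTable(
    "gX\tchr1\t?\t0\t100\t0\t100"), siP), "unknown strand")
  expect_error(readAnnotation(writeGeneTable(
    "gX\tchr1\t+\t100\t200\t50\t90"), siP), "exon outside gene span")
})

test_that("multi-transcript genes collapse to the longest transcript", {
  f <- writeGeneTable(c("gA\tchr1\t+\t10000\t15000\t10000\t15000",
                        twoExonPlus))
  ann <- readAnnotation(f, siP)
  expect_length(ann, 1L)
  expect_identical(unname(tes(ann)), 20000L)
  expect_length(readAnnotation(f, siP, collapse = "none"), 2L)
})

test_that("buildPartitions places promoter, first intron and intergenic regions", {
  ann <- readAnnotation(writeGeneTable(twoExonPlus), siP)
  parts <- buildPartitions(ann, siP)
  cats <- partitionCategories(parts)
  # promoter [TSS-2000, TSS+500) in BED coords = [8000, 10500)
  expect_equal(grToDf(cats$promoter), data.frame(start = 8001L, end = 10500L))
  expect_equal(grToDf(cats$intron_first),
               data.frame(start = 11001L, end = 19000L))
  expect_length(cats$intron_later, 0L)
  # intergenic = complement of body U promoter
  expect_equal(grToDf(cats$intergenic),
               data.frame(start = c(1L, 20001L), end = c(8000L, 100000L)))
  # on '-' the first intron flips to the same gap, and promoter mirrors
  annM <- readAnnotation(writeGeneTable(twoExonMinus), siP)
  catsM <- partitionCategories(buildPartitions(annM, siP))
  expect_equal(grToDf(catsM$intron_first),
               data.frame(start = 11001L, end = 19000L))
  expect_equal(grToDf(catsM$promoter),
               data.frame(start = 19501L, end = 22000L))
})

test_that("nested genes yield overlapping exon and intron footprints", {
  f <- writeGeneTable(c(twoExonPlus,
                        "gNest\tchr1\t+\t13000\t14000\t13000\t14000"))
  parts <- buildPartitions(readAnnotation(f, siP), siP)
  cats <- partitionCategories(parts)
  nest <- GRanges("chr1", IRanges(13001, 14000), seqinfo = siP)
  expect_true(any(pairwiseAnyOverlap(nest, cats$coding_exon)))
  expect_true(any(pairwiseAnyOverlap(nest, cats$intron_all)))
})

test_that("intergenic equals the per-base complement oracle on random toys", {
  set.seed(21)
  for (i in 1:5) {
    gs <- generateSynthetic(smallDesign(100 + i, nGenes = 20L,
                                        nBackgroundSites = 40L,
                                        tesGroupCounts = c(`500` = 5L,
                                                           `1000` = 5L,
                                                           none = 10L)))
    ann <- gs$bundle$genes
    parts <- buildPartitions(ann, gs$bundle$chromSizes)
    cats <- partitionCategories(parts)
    len <- unname(seqlengths(gs$bundle$chromSizes)[1])
    covered <- bitmapCover(c(granges(geneBodies(ann)), cats$promoter), len)
    r <- rle(!covered)
    ends <- cumsum(r$lengths)
    starts <- c(1L, head(ends, -1L) + 1L)
    oracle <- data.frame(start = starts[r$values], end = ends[r$values])
    expect_equal(grToDf(cats$intergenic), oracle, ignore_attr = TRUE)
  }
})

test_that("classifyPeaks counts non-exclusively and matches the all-pairs oracle", {
  ann <- readAnnotation(writeGeneTable(twoExonPlus), siP)
  parts <- buildPartitions(ann, siP)
  lonely <- PeakSet(GRanges("chr1", IRanges(30001, 30100), seqinfo = siP), "pk")
  cl <- classifyPeaks(lonely, parts)
  expect_identical(sum(cl$flags), 1L)
  expect_identical(unname(cl$counts["intergenic"]), 1L)
  # a peak spanning promoter + exon1 + intron1 carries >= 3 flags
  wide <- PeakSet(GRanges("chr1", IRanges(9001, 14000), seqinfo = siP), "pk")
  expect_gte(sum(classifyPeaks(wide, parts)$flags), 3L)
  # oracle agreement on random peaks
  set.seed(31)
  peaks <- randomIntervals(150, 90000, chrom = "chr1")
  peaks <- PeakSet(GRanges(seqnames(peaks), ranges(peaks), seqinfo = siP))
  cl <- classifyPeaks(peaks, parts)
  for (cat in names(cl$counts))
    expect_identical(unname(cl$flags[, cat]),
                     pairwiseAnyOverlap(granges(peaks),
                                        partitionCategories(parts)[[cat]]))
  # every peak receives at least one category flag
  expect_true(all(rowSums(cl$flags) >= 1L))
  expect_gte(sum(cl$counts), length(peaks))
})

test_that("category counts are invariant under genome mirroring", {
  gs <- generateSynthetic(smallDesign(55, nGenes = 30L, nBackgroundSites = 60L,
                                      tesGroupCounts = c(`500` = 8L,
                                                         `1000` = 7L,
                                                         none = 15L)))
  ann <- gs$bundle$genes
  si <- gs$bundle$chromSizes
  len <- unname(seqlengths(si)[1])
  cons <- replicateConsensus(gs$bundle$peaks$d0$rep1, gs$bundle$peaks$d0$rep2,
                             "d0")
  counts <- classifyPeaks(cons, buildPartitions(ann, si))$counts
  annM <- mirrorAnnotation(ann, len)
  consM <- PeakSet(mirrorGRanges(granges(cons), len))
  countsM <- classifyPeaks(consM, buildPartitions(annM, si))$counts
  expect_identical(counts, countsM)
})

test_that("length distributions summarize per category and tolerate empties", {
  ps <- PeakSet(GRanges("chr1", IRanges(c(30001, 40001, 50001),
                                        width = c(100, 200, 300)),
                        seqinfo = siP), "pk")
  overall <- lengthDistribution(ps)
  expect_identical(overall$median, 200)
  ann <- readAnnotation(writeGeneTable(twoExonPlus), siP)
  byCat <- lengthDistribution(ps, buildPartitions(ann, siP))
  expect_identical(byCat$n[byCat$category == "intergenic"], 3)
  expect_identical(byCat$n[byCat$category == "promoter"], 0)
  expect_true(is.na(byCat$median[byCat$category == "promoter"]))
})

test_that("generator length distribution recovers the planted median", {
  set.seed(61)
  lens <- pmin(pmax(round(rlnorm(2000, log(400), 0.6)), 50), 20000)
  expect_lt(abs(median(lens) - 400) / 400, 0.10)
})
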