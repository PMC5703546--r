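siS <- Seqinfo("chr1", 100000)

writeTmp <- function(lines, ext = ".bedgraph") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

constantTrack <- function(value, si = siS, bin = 25L) {
  nb <- ceiling(unname(seqlengths(si)) / bin)
  SignalTrack(setNames(list(rep(value, nb)), seqlevels(si)), si, bin)
}

# gene table row helper (BED-style 0-based columns)
geneRow <- function(id, strand, s, e)
  sprintf("%s\tchr1\t%s\t%d\t%d\t%d\t%d", id, strand, s, e, s, e)

annotationOf <- function(rows) {
  f <- writeTmp(rows, ".tsv")
  readAnnotation(f, siS)
}

test_that("readBedGraph bins values and agrees with per-base expansion", {
  expect_true(all(unlist(trackValues(
    readBedGraph(writeTmp(character(0)), siS))) == 0))
  tr <- readBedGraph(writeTmp("chr1\t0\t25\t4.0"), siS)
  v <- trackValues(tr)$chr1
  expect_equal(v[1], 4)
  expect_true(all(v[-1] == 0))
  # unsorted + overlapping records: per-base sum, then bin mean
  lines <- c("chr1\t30\t80\t2.0", "chr1\t0\t50\t1.0", "chr1\t40\t60\t0.5")
  tr2 <- readBedGraph(writeTmp(lines), siS)
  perBase <- numeric(100)
  perBase[31:80] <- perBase[31:80] + 2
  perBase[1:50] <- perBase[1:50] + 1
  perBase[41:60] <- perBase[41:60] + 0.5
  expect_equal(trackValues(tr2)$chr1[1:4], colMeans(matrix(perBase, nrow = 25)))
  expect_error(readBedGraph(writeTmp("chr1\t0\t10\t-1"), siS), "negative")
  expect_error(readBedGraph(writeTmp("chr1\t0\t200001\t1"), siS), "beyond")
})

test_that("maskToPeaks zeroes non-peak bins and never increases signal", {
  tr <- constantTrack(2)
  none <- maskToPeaks(tr, PeakSet(GRanges(seqinfo = siS), "none"))
  expect_true(all(unlist(trackValues(none)) == 0))
  whole <- maskToPeaks(tr, PeakSet(GRanges("chr1", IRanges(1, 100000),
                                           seqinfo = siS), "all"))
  expect_identical(trackValues(whole), trackValues(tr))
  set.seed(9)
  for (i in 1:10) {
    pk <- randomIntervals(30, 100000, chrom = "chr1")
    pk <- PeakSet(GRanges(seqnames(pk), ranges(pk), seqinfo = siS))
    masked <- maskToPeaks(tr, pk)
    v <- trackValues(masked)$chr1
    cover <- bitmapCover(granges(pk), 100000L)
    keepOracle <- vapply(seq_along(v), function(b)
      any(cover[((b - 1) * 25 + 1):min(b * 25, 100000)]), logical(1))
    expect_identical(v > 0, keepOracle)
    expect_true(all(v <= trackValues(tr)$chr1))
  }
})

test_that("tesProfile rows are flat on uniform signal with leftmost-tie summit", {
  ann <- annotationOf(geneRow("g1", "+", 10000, 20000))
  prof <- tesProfile(constantTrack(1), ann)
  m <- profileMatrix(prof)
  expect_identical(dim(m), c(1L, 160L))
  expect_true(all(m == 1))
  expect_identical(unname(summitOffsets(prof)["g1"]), binOffsets(prof)[1])
})

test_that("planted TES-flank bumps are localized within half a bin", {
  # triangular bump centered at TES+1000 of a '+' gene
  nb <- 4000L
  v <- numeric(nb)
  tes0 <- 20000L
  apex <- tes0 + 1000L
  for (b in seq.int((apex - 300) %/% 25, (apex + 300) %/% 25 + 1)) {
    center <- (b - 0.5) * 25
    v[b] <- max(0, 1 - abs(center - apex) / 300)
  }
  tr <- SignalTrack(list(chr1 = v), siS, 25L)
  annP <- annotationOf(geneRow("g1", "+", 10000, 20000))
  profP <- tesProfile(tr, annP)
  expect_lte(abs(unname(summitOffsets(profP)["g1"]) - 1000), 12.5)
  # mirrored geometry on a '-' gene gives the identical row
  len <- 100000L
  vM <- rev(v)
  annM <- annotationOf(geneRow("g1", "-", len - 20000L, len - 10000L))
  profM <- tesProfile(SignalTrack(list(chr1 = vM), siS, 25L), annM)
  expect_equal(unname(profileMatrix(profM)), unname(profileMatrix(profP)))
})

test_that("metagene profiles rescale bodies onto aligned quantile columns", {
  ann <- annotationOf(geneRow("g1", "+", 10000, 20000))
  mg <- metageneProfile(constantTrack(3), ann)
  expect_identical(ncol(mg$profile), 80L + 100L + 80L)
  expect_true(all(mg$profile == 3))
  expect_true(all(mg$se == 0))
  # bump at the TSS peaks at the body start boundary
  v <- numeric(4000)
  v[(10000 %/% 25):(10000 %/% 25 + 8)] <- 5
  tr <- SignalTrack(list(chr1 = v), siS, 25L)
  mgB <- metageneProfile(tr, ann)
  peakCol <- which.max(mgB$mean)
  expect_lte(abs(peakCol - 80L), 2L)
  # proportionally positioned bumps align after rescaling
  rows <- c(geneRow("gShort", "+", 30000, 35000), geneRow("gLong", "+", 50000, 70000))
  ann2 <- annotationOf(rows)
  v2 <- numeric(4000)
  v2[(32500 %/% 25):(32500 %/% 25 + 2)] <- 4   # midpoint of gShort
  v2[(60000 %/% 25):(60000 %/% 25 + 8)] <- 4   # midpoint of gLong
  mg2 <- metageneProfile(SignalTrack(list(chr1 = v2), siS, 25L), ann2)
  peaks <- apply(mg2$profile[, 81:180], 1, which.max)
  expect_lte(abs(diff(peaks)), 2L)
})

test_that("aggregateGroup averages rows with exact SE behaviour", {
  ann <- annotationOf(c(geneRow("g1", "+", 10000, 20000),
                        geneRow("g2", "+", 40000, 50000)))
  prof <- tesProfile(constantTrack(2), ann)
  single <- aggregateGroup(prof, "g1")
  expect_equal(unname(single$mean), unname(profileMatrix(prof)["g1", ]))
  expect_true(all(single$se == 0))
  both <- aggregateGroup(prof, c("g1", "g2"))
  expect_true(all(both$se == 0))  # identical rows
  expect_error(aggregateGroup(prof, character(0)), "empty")
  expect_error(aggregateGroup(prof, "nope"), "not in profile")
})

test_that("classifyTesFlank applies window, downstream and summit rules", {
  mkProfile <- function(offsets, values, rowsBase = 0) {
    n <- 160L
    binOff <- -2000 + (seq_len(n) - 0.5) * 25
    prof <- matrix(rowsBase, nrow = length(offsets), ncol = n,
                   dimnames = list(paste0("g", seq_along(offsets)), NULL))
    for (i in seq_along(offsets)) {
      j <- which.min(abs(binOff - offsets[i]))
      prof[i, j] <- values[i]
    }
    new("TESProfileMatrix", profile = prof, binWidth = 25L, flank = 2000L,
        binOffsets = binOff,
        summitOffset = binOff[apply(prof, 1, which.max)],
        summitValue = apply(prof, 1, max))
  }
  mat <- mkProfile(c(1005, -500, 520), c(5, 5, 5))
  got <- classifyTesFlank(mat)
  expect_identical(as.character(got$group),
                   c("TES_PLUS_1000", "NONE", "TES_PLUS_500"))
  # below the absolute summit floor everything is NONE
  expect_true(all(classifyTesFlank(mat, minSummit = 10)$group == "NONE"))
  expect_error(classifyTesFlank(mat, centers = c(400, 600), tolerance = 250),
               "overlap")
})

test_that("TES group recovery from the generator meets planted-truth targets", {
  # noise-free: perfect recovery through the masked pipeline
  noise0 <- cachedRun("small_noise0", smallDesign(17, noiseLevel = 0))
  expect_identical(noise0$verify$tes_recovery, 1)
  # default noise, unmasked track (harder): >= 90% recovery
  gs <- cachedRun("default_run", syntheticDesign(seed = 23))$gs
  prof <- suppressWarnings(tesProfile(gs$bundle$tracks$d9, gs$bundle$genes))
  tg <- classifyTesFlank(prof)
  expect_gte(mean(as.character(tg$group) == gs$truth$tes_groups[tg$gene_id]),
             0.90)
})

test_that("TES profiles are invariant under genome mirroring", {
  gs <- generateSynthetic(smallDesign(71, nGenes = 30L, nBackgroundSites = 50L,
                                      tesGroupCounts = c(`500` = 8L,
                                                         `1000` = 7L,
                                                         none = 15L)))
  tr <- gs$bundle$tracks$d9
  len <- unname(seqlengths(gs$bundle$chromSizes)[1])
  prof <- suppressWarnings(tesProfile(tr, gs$bundle$genes))
  trM <- SignalTrack(lapply(trackValues(tr), rev), gs$bundle$chromSizes,
                     binWidth(tr))
  annM <- mirrorAnnotation(gs$bundle$genes, len)
  profM <- suppressWarnings(tesProfile(trM, annM))
  ids <- rownames(profileMatrix(prof))
  expect_equal(profileMatrix(profM)[ids, ], profileMatrix(prof)[ids, ])
})
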