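# Independent per-base / all-pairs oracles for toy genomes (1-based closed
# coordinates throughout, matching the GRanges convention used internally).

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(GenomeInfoDb)
})

toySeqinfo <- function(len = 10000L, chrom = "chrT") Seqinfo(chrom, len)

randomIntervals <- function(n, len, minW = 5L, maxW = 400L, chrom = "chrT") {
  w <- sample(minW:maxW, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(len - wi, 1L), integer(1))
  GRanges(chrom, IRanges(s, s + w - 1L), seqinfo = Seqinfo(chrom, len))
}

# per-base bitmap of covered positions
bitmapCover <- function(gr, len) {
  b <- logical(len)
  for (i in seq_along(gr)) b[start(gr)[i]:end(gr)[i]] <- TRUE
  b
}

# single-linkage merge with gap bridging, via run detection on the bitmap
bitmapMerge <- function(gr, len, gap = 0L) {
  b <- bitmapCover(gr, len)
  r <- rle(b)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (gap > 0L && nrow(runs) > 1L) {
    out <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      if (runs$start[i] - out$end[nrow(out)] - 1L <= gap)
        out$end[nrow(out)] <- runs$end[i]
      else out <- rbind(out, runs[i, ])
    }
    runs <- out
  }
  runs
}

# all-pairs overlap test between two interval sets (>= 1 shared base)
pairwiseAnyOverlap <- function(query, subject) {
  vapply(seq_along(query), function(i) {
    any(as.character(seqnames(subject)) == as.character(seqnames(query)[i]) &
          start(subject) <= end(query)[i] & end(subject) >= start(query)[i])
  }, logical(1))
}

# Venn pattern counts over the merged union of several sets, per-base
bitmapVennCounts <- function(sets, len) {
  bits <- lapply(sets, bitmapCover, len = len)
  universe <- Reduce(`|`, bits)
  r <- rle(universe)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  pat <- vapply(seq_len(nrow(runs)), function(i) {
    hit <- vapply(bits, function(b) any(b[runs$start[i]:runs$end[i]]),
                  logical(1))
    paste(names(sets)[hit], collapse = "&")
  }, character(1))
  table(pat)
}

grToDf <- function(gr) data.frame(start = start(gr), end = end(gr))

mirrorGRanges <- function(gr, len, resort = TRUE) {
  out <- GRanges(seqnames(gr), IRanges(len - end(gr) + 1L, len - start(gr) + 1L),
                 strand = chartr("+-", "-+", as.character(strand(gr))),
                 seqinfo = seqinfo(gr))
  mcols(out) <- mcols(gr)
  if (resort) sort(out, ignore.strand = TRUE) else out
}

mirrorAnnotation <- function(ann, len) {
  g <- geneBodies(ann)
  gm <- mirrorGRanges(g, len, resort = FALSE)  # keep gene <-> exon pairing
  names(gm) <- names(g)
  exm <- GRangesList(lapply(seq_along(g), function(i)
    mirrorGRanges(geneExons(ann)[[i]], len)))
  names(exm) <- names(g)
  new("GeneAnnotation", genes = gm, exons = exm)
}

# small generator designs used across tests (kept desk-sized for speed)
smallDesign <- function(seed, ...) {
  args <- utils::modifyList(
    list(seed = seed, nChrom = 1L, chromLength = 1500000,
         nGenes = 60L, nBackgroundSites = 120L,
         tesGroupCounts = c(`500` = 15L, `1000` = 15L, none = 30L)),
    list(...))
  do.call(syntheticDesign, args)
}

# cache of the default-design run shared by acceptance-style tests
.runCache <- new.env(parent = emptyenv())
cachedRun <- function(key, design) {
  if (is.null(.runCache[[key]])) {
    gs <- generateSynthetic(design)
    rep <- runBundle(gs$bundle)
    .runCache[[key]] <- list(gs = gs, report = rep,
                             verify = verifyTruth(rep, gs$truth))
  }
  .runCache[[key]]
}
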