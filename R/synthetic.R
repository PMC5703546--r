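#' Describe a synthetic study design
#'
#' Encodes the conditions emulated by the generator: three differentiation
#' stages with two biological replicates each, a merged-union site universe
#' with controlled stage membership, replicate concordance around 45% (the
#' share of replicate-1 calls supported by replicate 2), log-normal site
#' lengths with median ~400 bp clamped to \[50 bp, 20 kb\], TF co-occupancy
#' fractions, genes carrying TES-flank accessibility bumps at +500 or +1000
#' bp, and >= 2-fold expression changes tied to those bump groups with a
#' controlled fidelity.
#'
#' `patternFractions` defaults mirror the observed three-stage Venn
#' proportions (all-three ~0.34; stage-exclusive ~0.21/0.07/0.08 for the
#' three stages in order; remainder split evenly among the pairwise
#' patterns).
#'
#' @param seed integer RNG seed driving all sub-generators.
#' @param nChrom,chromLength genome shape (default 2 x 3 Mb).
#' @param stages stage names, earliest first.
#' @param nBackgroundSites size of the planted background site universe
#'   (flank-bump sites for TES-group genes are added on top).
#' @param patternFractions named fractions over stage-membership patterns
#'   (names like `"d0"`, `"d0&d9"`); must sum to 1.
#' @param replicateConcordance probability a planted stage site is supported
#'   by both replicates (discordant sites appear in one replicate only and
#'   are dropped by the consensus rule).
#' @param lengthMeanLog,lengthSdLog log-normal site length parameters.
#' @param minLength,maxLength site length clamp in bp.
#' @param jitterBp maximum +/- jitter of replicate peak edges in bp.
#' @param tfFractions named fractions (`runx2_only`, `ctcf_only`, `both`) of
#'   a stage's sites co-occupied by the TFs; remainder is neither.
#' @param tfOutside named fractions (`runx2`, `ctcf`) of TF peaks falling
#'   outside any DHS site.
#' @param nGenes total gene models.
#' @param tesGroupCounts named counts of genes planted with a flank bump at
#'   `+500` / `+1000` / `none`.
#' @param expressionFidelity probability a +1000 gene is planted UP and a
#'   +500 gene DOWN (misses become UNCHANGED).
#' @param upFold,downFold planted linear fold changes for UP / DOWN genes.
#' @param bumpHeight flank-bump signal height (arbitrary normalized units).
#' @param noiseLevel amplitude of per-bin uniform background noise in the
#'   coverage tracks (0 disables noise).
#' @param binWidth signal track bin width in bp.
#' @return a `SyntheticDesign` (validated list).
#' @export
syntheticDesign <- function(seed = 1L,
                            nChrom = 2L, chromLength = 3e6,
                            stages = c("d0", "d9", "d28"),
                            nBackgroundSites = 400L,
                            patternFractions = NULL,
                            replicateConcordance = 0.45,
                            lengthMeanLog = log(400), lengthSdLog = 0.6,
                            minLength = 50L, maxLength = 20000L,
                            jitterBp = 10L,
                            tfFractions = c(runx2_only = 0.226,
                                            ctcf_only = 0.16, both = 0.10),
                            tfOutside = c(runx2 = 0.37, ctcf = 0.30),
                            nGenes = 200L,
                            tesGroupCounts = c(`500` = 50L, `1000` = 50L,
                                               none = 100L),
                            expressionFidelity = 0.9,
                            upFold = 4, downFold = 0.25,
                            bumpHeight = 1.0,
                            noiseLevel = 0.25,
                            binWidth = 25L) {
  if (is.null(patternFractions)) {
    k <- length(stages)
    stopifnot(k == 3L)
    excl <- setNames(c(0.2091, 0.0693, 0.0823), stages)
    all3 <- 0.3355
    pairs <- utils::combn(stages, 2L, paste, collapse = "&")
    rest <- (1 - all3 - sum(excl)) / length(pairs)
    patternFractions <- c(excl, setNames(rep(rest, length(pairs)), pairs),
                          setNames(all3, paste(stages, collapse = "&")))
  }
  design <- list(seed = as.integer(seed), nChrom = as.integer(nChrom),
                 chromLength = as.integer(chromLength), stages = stages,
                 nBackgroundSites = as.integer(nBackgroundSites),
                 patternFractions = patternFractions,
                 replicateConcordance = replicateConcordance,
                 lengthMeanLog = lengthMeanLog, lengthSdLog = lengthSdLog,
                 minLength = as.integer(minLength),
                 maxLength = as.integer(maxLength),
                 jitterBp = as.integer(jitterBp),
                 tfFractions = tfFractions, tfOutside = tfOutside,
                 nGenes = as.integer(nGenes),
                 tesGroupCounts = tesGroupCounts,
                 expressionFidelity = expressionFidelity,
                 upFold = upFold, downFold = downFold,
                 bumpHeight = bumpHeight, noiseLevel = noiseLevel,
                 binWidth = as.integer(binWidth))
  frs <- c(design$patternFractions, design$tfFractions,
           replicateConcordance, expressionFidelity)
  if (any(frs < 0 | frs > 1)) stop("all fractions must lie in [0, 1]")
  if (abs(sum(design$patternFractions) - 1) > 1e-8)
    stop("'patternFractions' must sum to 1")
  if (sum(design$tfFractions) > 1) stop("'tfFractions' must sum to <= 1")
  if (sum(design$tesGroupCounts) != design$nGenes)
    stop("'tesGroupCounts' must sum to 'nGenes'")
  if (design$noiseLevel < 0 || design$bumpHeight <= 0)
    stop("bad signal parameters")
  class(design) <- "SyntheticDesign"
  design
}

# largest-remainder allocation of n among fractions (sums exactly to n)
.allocate <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  extra <- n - sum(base)
  if (extra > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  setNames(as.integer(base), names(fractions))
}

# place intervals of given lengths in free segments, keeping >= minGap bp
# between placed intervals; errors when the design does not fit
.placeIntervals <- function(segs, lens, minGap) {
  out <- data.frame(chrom = character(length(lens)),
                    start = integer(length(lens)), end = integer(length(lens)),
                    stringsAsFactors = FALSE)
  for (i in seq_along(lens)) {
    len <- lens[i]
    fits <- which(segs$end - segs$start + 1L >= len)
    if (!length(fits))
      stop("infeasible design: cannot place ", length(lens),
           " sites of the requested lengths in the genome")
    wts <- (segs$end - segs$start + 1L - len + 1L)[fits]
    j <- fits[sample.int(length(fits), 1L, prob = wts)]
    s <- segs$start[j] + sample.int(segs$end[j] - segs$start[j] + 2L - len, 1L) - 1L
    e <- s + len - 1L
    out$chrom[i] <- segs$chrom[j]; out$start[i] <- s; out$end[i] <- e
    left <- data.frame(chrom = segs$chrom[j], start = segs$start[j],
                       end = s - minGap - 1L, stringsAsFactors = FALSE)
    right <- data.frame(chrom = segs$chrom[j], start = e + minGap + 1L,
                        end = segs$end[j], stringsAsFactors = FALSE)
    segs <- rbind(segs[-j, , drop = FALSE],
                  left[left$end - left$start + 1L >= 1L, , drop = FALSE],
                  right[right$end - right$start + 1L >= 1L, , drop = FALSE])
  }
  out
}

.triangleAdd <- function(values, binWidth, s, e, h) {
  # add a triangular kernel (apex at the interval midpoint) to binned values
  m <- (s + e) / 2
  w <- (e - s + 1) / 2
  b1 <- (s - 1L) %/% binWidth + 1L
  b2 <- min((e - 1L) %/% binWidth + 1L, length(values))
  bins <- b1:b2
  centers <- (bins - 0.5) * binWidth
  values[bins] <- values[bins] + h * pmax(0, 1 - abs(centers - m) / w)
  values
}

#' Generate a synthetic data bundle with planted ground truth
#'
#' Builds a toy genome, collapsed gene models, per-stage/per-replicate peak
#' calls, TF ChIP peak sets with controlled DHS co-occupancy, per-stage
#' coverage tracks (triangular site bumps plus uniform background noise) and
#' a per-stage expression table — together with a truth table recording every
#' planted label. Identical seeds yield identical bundles (and byte-identical
#' files when `outdir` is given).
#'
#' Planted sites are spaced well apart (never book-ended) so merged-union
#' counting cannot fuse distinct truth sites, and background sites avoid all
#' TES +/- 2.6 kb windows so flank-bump classification has a clean truth.
#' Genes in the `+500`/`+1000` groups receive a dedicated flank site
#' (present and concordant in every stage) centered at that downstream
#' offset; its triangular bump is what the TES profiler must recover.
#'
#' @param design a [syntheticDesign()].
#' @param outdir directory to write the file bundle into, or `NULL` for an
#'   in-memory bundle only.
#' @return list with `bundle` (chromSizes, genes, peaks, tf, tracks,
#'   expression), `truth` (per-site and per-gene planted labels and realized
#'   summary counts) and `files` (named paths, or `NULL`).
#' @export
generateSynthetic <- function(design, outdir = NULL) {
  stopifnot(inherits(design, "SyntheticDesign"))
  set.seed(design$seed)
  subseed <- sample.int(.Machine$integer.max - 1L, 6L)

  chroms <- paste0("chr", seq_len(design$nChrom))
  si <- Seqinfo(chroms, rep(design$chromLength, design$nChrom))
  stages <- design$stages

  ## 1. gene models ---------------------------------------------------
  set.seed(subseed[1])
  margin <- 5000L
  geneRows <- list(); ch <- 1L; x <- margin + 1L
  for (i in seq_len(design$nGenes)) {
    len <- as.integer(round(runif(1, 7000, 12000)))
    while (ch <= length(chroms) && x + len > design$chromLength - margin) {
      ch <- ch + 1L; x <- margin + 1L
    }
    if (ch > length(chroms))
      stop("infeasible design: genome too small for ", design$nGenes, " genes")
    strand <- sample(c("+", "-"), 1L)
    e1 <- as.integer(round(runif(1, 200, 500)))
    e2 <- as.integer(round(runif(1, 150, 400)))
    e3 <- as.integer(round(runif(1, 200, 500)))
    restLen <- len - e1 - e2 - e3
    i1 <- as.integer(round(restLen * runif(1, 0.3, 0.7)))
    s <- x
    exS <- c(s, s + e1 + i1, s + len - e3)
    exE <- c(s + e1 - 1L, s + e1 + i1 + e2 - 1L, s + len - 1L)
    geneRows[[i]] <- list(id = sprintf("gene%03d", i), chrom = chroms[ch],
                          strand = strand, start = s, end = s + len - 1L,
                          exS = exS, exE = exE)
    x <- x + len + as.integer(round(runif(1, 6000, 9000)))
  }
  genesGr <- GRanges(vapply(geneRows, `[[`, character(1), "chrom"),
                     IRanges(vapply(geneRows, `[[`, numeric(1), "start"),
                             vapply(geneRows, `[[`, numeric(1), "end")),
                     strand = vapply(geneRows, `[[`, character(1), "strand"),
                     seqinfo = si)
  names(genesGr) <- vapply(geneRows, `[[`, character(1), "id")
  exonsGrl <- GRangesList(lapply(geneRows, function(r)
    GRanges(r$chrom, IRanges(r$exS, r$exE), strand = r$strand, seqinfo = si)))
  names(exonsGrl) <- names(genesGr)
  genes <- new("GeneAnnotation", genes = genesGr, exons = exonsGrl)

  ## 2. TES groups and flank sites ------------------------------------
  set.seed(subseed[2])
  grpLabels <- c(rep("TES_PLUS_500", design$tesGroupCounts[["500"]]),
                 rep("TES_PLUS_1000", design$tesGroupCounts[["1000"]]),
                 rep("NONE", design$tesGroupCounts[["none"]]))
  tesGroup <- setNames(sample(grpLabels), names(genesGr))
  tesPos <- tes(genes)  # 1-based TES base
  flankHalf <- 300L
  flankSites <- do.call(rbind, lapply(names(genesGr)[tesGroup != "NONE"],
    function(id) {
      c0 <- if (tesGroup[[id]] == "TES_PLUS_500") 500L else 1000L
      plus <- as.character(strand(genesGr[id])) == "+"
      t0 <- if (plus) end(genesGr[id]) else start(genesGr[id]) - 1L
      center <- if (plus) t0 + c0 else t0 + 1L - c0
      data.frame(chrom = as.character(seqnames(genesGr[id])),
                 start = center - flankHalf, end = center + flankHalf,
                 gene = id, stringsAsFactors = FALSE)
    }))

  ## 3. background site universe --------------------------------------
  set.seed(subseed[3])
  forb <- GRanges(seqnames(genesGr),
                  IRanges(pmax(1L, ifelse(as.character(strand(genesGr)) == "+",
                                          end(genesGr), start(genesGr)) - 2600L),
                          pmin(design$chromLength,
                               ifelse(as.character(strand(genesGr)) == "+",
                                      end(genesGr), start(genesGr)) + 2600L)),
                  seqinfo = si)
  allowed <- gaps(GenomicRanges::reduce(c(granges(forb),
    GRanges(chroms, IRanges(1, margin), seqinfo = si),
    GRanges(chroms, IRanges(design$chromLength - margin, design$chromLength),
            seqinfo = si))))
  allowed <- allowed[strand(allowed) == "*"]
  segs <- data.frame(chrom = as.character(seqnames(allowed)),
                     start = start(allowed), end = end(allowed),
                     stringsAsFactors = FALSE)
  lens <- pmin(pmax(as.integer(round(rlnorm(design$nBackgroundSites,
                                            design$lengthMeanLog,
                                            design$lengthSdLog))),
                    design$minLength), design$maxLength)
  minGap <- 2L * design$jitterBp + 30L
  bg <- .placeIntervals(segs, lens, minGap)
  patternNames <- names(design$patternFractions)
  patCounts <- .allocate(design$nBackgroundSites, design$patternFractions)
  bg$pattern <- sample(rep(patternNames, patCounts))
  bg$gene <- NA_character_

  sites <- bg[, c("chrom", "start", "end", "pattern", "gene")]
  if (!is.null(flankSites) && nrow(flankSites))
    sites <- rbind(sites,
                   data.frame(chrom = flankSites$chrom,
                              start = flankSites$start, end = flankSites$end,
                              pattern = paste(stages, collapse = "&"),
                              gene = flankSites$gene, stringsAsFactors = FALSE))
  sites$isFlank <- !is.na(sites$gene)
  sites$height <- ifelse(sites$isFlank, design$bumpHeight, runif(nrow(sites), 0.5, 2))
  o <- order(match(sites$chrom, chroms), sites$start)
  sites <- sites[o, ]; rownames(sites) <- NULL
  sites$site_id <- sprintf("site%04d", seq_len(nrow(sites)))

  ## 4. replicate peaks and realized consensus membership -------------
  set.seed(subseed[4])
  planted <- lapply(stages, function(st)
    grepl(paste0("(^|&)", st, "(&|$)"), sites$pattern))
  names(planted) <- stages
  concord <- lapply(stages, function(st)
    ifelse(sites$isFlank, TRUE,
           runif(nrow(sites)) < design$replicateConcordance))
  names(concord) <- stages
  inCons <- lapply(stages, function(st) planted[[st]] & concord[[st]])
  names(inCons) <- stages
  jit <- function(n) sample(seq(-design$jitterBp, design$jitterBp), n,
                            replace = TRUE)
  peaks <- list()
  for (st in stages) {
    reps <- list()
    # concordant sites appear in both replicates, discordant in one only
    solo <- planted[[st]] & !concord[[st]]
    soloRep <- ifelse(runif(nrow(sites)) < 0.5, 1L, 2L)
    for (rp in 1:2) {
      use <- inCons[[st]] | (solo & soloRep == rp)
      n <- sum(use)
      s <- pmax(1L, sites$start[use] + jit(n))
      e <- pmin(design$chromLength, sites$end[use] + jit(n))
      gr <- GRanges(sites$chrom[use], IRanges(s, pmax(e, s + design$minLength - 1L)),
                    seqinfo = si)
      reps[[paste0("rep", rp)]] <- PeakSet(gr, label = paste0(st, "_rep", rp))
    }
    peaks[[st]] <- reps
  }

  ## 5. TF peaks with controlled co-occupancy -------------------------
  set.seed(subseed[5])
  tfWidth <- 150L
  allSitesGr <- GRanges(sites$chrom, IRanges(sites$start, sites$end),
                        seqinfo = si)
  tfFree <- gaps(GenomicRanges::reduce(c(
    granges(allSitesGr) + (design$jitterBp + 50L), granges(forb),
    GRanges(chroms, IRanges(1, margin), seqinfo = si),
    GRanges(chroms, IRanges(design$chromLength - margin, design$chromLength),
            seqinfo = si))))
  tfFree <- tfFree[strand(tfFree) == "*"]
  tfSegs <- data.frame(chrom = as.character(seqnames(tfFree)),
                       start = start(tfFree), end = end(tfFree),
                       stringsAsFactors = FALSE)
  tf <- list(); tfTruth <- list()
  fr <- c(design$tfFractions,
          neither = 1 - sum(design$tfFractions))
  for (st in stages) {
    idx <- which(inCons[[st]])
    n <- length(idx)
    cls <- .allocate(n, fr)
    assign <- sample(rep(names(cls), cls))
    inner <- function(which) {
      take <- idx[assign %in% which]
      if (!length(take)) return(GRanges(seqinfo = si))
      mid <- (sites$start[take] + sites$end[take]) %/% 2L
      off <- vapply(sites$end[take] - sites$start[take] + 1L, function(w)
        sample.int(max(1L, w %/% 4L), 1L) - as.integer(w %/% 8L), integer(1))
      s <- pmax(sites$start[take], mid + off - tfWidth %/% 2L)
      GRanges(sites$chrom[take],
              IRanges(s, pmin(sites$end[take], s + tfWidth - 1L)), seqinfo = si)
    }
    r2in <- inner(c("runx2_only", "both"))
    ctin <- inner(c("ctcf_only", "both"))
    nOut <- function(nin, frac) as.integer(round(nin * frac / (1 - frac)))
    oR <- nOut(length(r2in), design$tfOutside[["runx2"]])
    oC <- nOut(length(ctin), design$tfOutside[["ctcf"]])
    placed <- .placeIntervals(tfSegs, rep(tfWidth, oR + oC), 10L)
    outGr <- GRanges(placed$chrom, IRanges(placed$start, placed$end),
                     seqinfo = si)
    tf[[st]] <- list(
      runx2 = PeakSet(c(r2in, head(outGr, oR)), label = paste0(st, "_runx2")),
      ctcf = PeakSet(c(ctin, tail(outGr, oC)), label = paste0(st, "_ctcf")))
    tfTruth[[st]] <- list(counts = as.list(cls),
                          runx2_total = length(r2in) + oR,
                          ctcf_total = length(ctin) + oC,
                          runx2_outside = oR, ctcf_outside = oC)
  }

  ## 6. coverage tracks ------------------------------------------------
  set.seed(subseed[6])
  nb <- ceiling(design$chromLength / design$binWidth)
  tracks <- list()
  for (st in stages) {
    values <- lapply(chroms, function(cc) numeric(nb))
    names(values) <- chroms
    use <- which(inCons[[st]])
    for (i in use) {
      cc <- sites$chrom[i]
      values[[cc]] <- .triangleAdd(values[[cc]], design$binWidth,
                                   sites$start[i], sites$end[i],
                                   sites$height[i])
    }
    if (design$noiseLevel > 0)
      values <- lapply(values, function(v)
        v + runif(length(v), 0, design$noiseLevel))
    tracks[[st]] <- SignalTrack(values, si, design$binWidth)
  }

  ## 7. expression table -----------------------------------------------
  exprClass <- setNames(rep("UNCHANGED", design$nGenes), names(genesGr))
  faithful <- runif(design$nGenes) < design$expressionFidelity
  exprClass[tesGroup == "TES_PLUS_1000" & faithful] <- "UP"
  exprClass[tesGroup == "TES_PLUS_500" & faithful] <- "DOWN"
  base <- rlnorm(design$nGenes, log(100), 0.5)
  fold <- ifelse(exprClass == "UP", design$upFold,
                 ifelse(exprClass == "DOWN", design$downFold,
                        2^runif(design$nGenes, -0.4, 0.4)))
  expr <- data.frame(row.names = names(genesGr))
  expr[[stages[1]]] <- round(base, 3)
  expr[[stages[2]]] <- round(base * fold, 3)
  if (length(stages) > 2)
    for (st in stages[-(1:2)])
      expr[[st]] <- round(base * fold * 2^runif(design$nGenes, -0.3, 0.3), 3)

  ## truth table -------------------------------------------------------
  realizedPattern <- vapply(seq_len(nrow(sites)), function(i) {
    inn <- stages[vapply(stages, function(st) inCons[[st]][i], logical(1))]
    paste(inn, collapse = "&")
  }, character(1))
  truthSites <- cbind(sites,
                      realized_pattern = realizedPattern,
                      stringsAsFactors = FALSE)
  patTab <- table(realizedPattern[nzchar(realizedPattern)])
  truth <- list(
    sites = truthSites,
    consensus_counts = setNames(vapply(stages, function(st)
      sum(inCons[[st]]), integer(1)), stages),
    pattern_counts = setNames(as.integer(patTab), names(patTab)),
    unique_sites = sum(nzchar(realizedPattern)),
    tf = tfTruth,
    tes_groups = tesGroup,
    expression_classes = exprClass,
    design = design[setdiff(names(design), "call")]
  )

  bundle <- list(chromSizes = si, genes = genes, peaks = peaks, tf = tf,
                 tracks = tracks, expression = expr, stages = stages,
                 design = design)
  files <- NULL
  if (!is.null(outdir)) files <- .writeBundle(bundle, truth, outdir)
  list(bundle = bundle, truth = truth, files = files)
}

# write the bundle in the exact formats the pipeline consumes
.writeBundle <- function(bundle, truth, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  si <- bundle$chromSizes
  files <- list()
  p <- function(...) file.path(outdir, paste0(...))
  write.table(data.frame(names(seqlengths(si)), unname(seqlengths(si))),
              files$chrom_sizes <- p("chrom.sizes"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  g <- geneBodies(bundle$genes); ex <- geneExons(bundle$genes)
  gt <- data.frame(gene_id = names(g), chrom = as.character(seqnames(g)),
                   strand = as.character(strand(g)),
                   txStart = start(g) - 1L, txEnd = end(g),
                   exonStarts = vapply(start(ex), function(s)
                     paste(s - 1L, collapse = ","), character(1)),
                   exonEnds = vapply(end(ex), function(e)
                     paste(e, collapse = ","), character(1)))
  write.table(gt, files$annotation <- p("genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  for (st in bundle$stages) {
    for (rp in names(bundle$peaks[[st]]))
      writeBed(bundle$peaks[[st]][[rp]],
               files[[paste0("peaks_", st, "_", rp)]] <- p(st, "_", rp, ".bed"))
    writeBed(bundle$tf[[st]]$runx2,
             files[[paste0("runx2_", st)]] <- p(st, "_runx2.bed"))
    writeBed(bundle$tf[[st]]$ctcf,
             files[[paste0("ctcf_", st)]] <- p(st, "_ctcf.bed"))
    tr <- bundle$tracks[[st]]
    con <- file(files[[paste0("track_", st)]] <- p(st, ".bedgraph"), "wt")
    bw <- binWidth(tr)
    for (cc in names(trackValues(tr))) {
      v <- trackValues(tr)[[cc]]
      r <- S4Vectors::Rle(round(v, 6))
      ends <- cumsum(S4Vectors::runLength(r))
      starts <- c(1L, head(ends, -1L) + 1L)
      vals <- S4Vectors::runValue(r)
      keep <- vals != 0
      if (any(keep)) {
        len <- seqlengths(si)[[cc]]
        writeLines(paste(cc, (starts[keep] - 1L) * bw,
                         pmin(ends[keep] * bw, len),
                         sprintf("%.6f", vals[keep]),
                         sep = "\t"), con)
      }
    }
    close(con)
  }
  expr <- bundle$expression
  write.table(cbind(gene_id = rownames(expr), expr),
              files$expression <- p("expression.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truthJson <- truth[setdiff(names(truth), "design")]
  for (f in c("consensus_counts", "pattern_counts", "tes_groups",
              "expression_classes"))
    truthJson[[f]] <- as.list(truthJson[[f]])
  jsonlite::write_json(truthJson, files$truth <- p("truth.json"),
                       auto_unbox = TRUE, digits = NA)
  designJson <- lapply(unclass(bundle$design), function(x)
    if (!is.null(names(x))) as.list(x) else x)
  jsonlite::write_json(designJson, files$design <- p("design.json"),
                       auto_unbox = TRUE, digits = NA)
  files
}
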