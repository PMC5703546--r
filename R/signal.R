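#' Construct a SignalTrack from per-chromosome bin values
#'
#' @param values named list of numeric vectors (one per chromosome,
#'   `ceiling(len/binWidth)` bins each).
#' @param chromsizes a `Seqinfo`.
#' @param binWidth bin width in bp (default 25).
#' @return a [SignalTrack].
#' @export
SignalTrack <- function(values, chromsizes, binWidth = 25L) {
  new("SignalTrack", values = values[names(seqlengths(chromsizes))],
      binWidth = as.integer(binWidth), seqinfo = chromsizes)
}

#' Read a bedGraph into a fixed-bin SignalTrack
#'
#' Four tab-separated columns (chrom, start, end, value; 0-based half-open).
#' Records may be unsorted or overlapping; the per-base value is the sum of
#' all records covering that base, and each bin stores the mean over its
#' in-genome bases (unspecified bases count as 0). The last bin of a
#' chromosome may be partial and averages only existing bases.
#'
#' @param path file path.
#' @param chromsizes a `Seqinfo`.
#' @param binWidth bin width in bp (default 25).
#' @return a [SignalTrack].
#' @export
readBedGraph <- function(path, chromsizes, binWidth = 25L) {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  parsed <- .splitBedLines(path)
  sl <- seqlengths(chromsizes)
  if (length(parsed$fields)) {
    nf <- lengths(parsed$fields)
    if (any(nf < 4L))
      stop("bedGraph parse error at line ", parsed$lineno[which(nf < 4L)[1]],
           ": fewer than 4 fields")
    chrom <- vapply(parsed$fields, `[[`, character(1), 1L)
    s0 <- as.numeric(vapply(parsed$fields, `[[`, character(1), 2L))
    e0 <- as.numeric(vapply(parsed$fields, `[[`, character(1), 3L))
    val <- as.numeric(vapply(parsed$fields, `[[`, character(1), 4L))
    bad <- is.na(s0) | is.na(e0) | is.na(val) | s0 < 0 | s0 >= e0
    if (any(bad))
      stop("bedGraph parse error at line ", parsed$lineno[which(bad)[1]],
           ": malformed record")
    if (any(val < 0))
      stop("bedGraph parse error at line ", parsed$lineno[which(val < 0)[1]],
           ": negative value")
    unknown <- !(chrom %in% names(sl))
    if (any(unknown))
      stop("bedGraph parse error at line ", parsed$lineno[which(unknown)[1]],
           ": unknown chromosome '", chrom[which(unknown)[1]], "'")
    beyond <- e0 > sl[chrom]
    if (any(beyond))
      stop("bedGraph parse error at line ", parsed$lineno[which(beyond)[1]],
           ": coordinates beyond chromosome length")
    gr <- GRanges(chrom, IRanges(s0 + 1, e0), seqinfo = chromsizes)
    cov <- GenomicRanges::coverage(gr, weight = val)
  } else {
    cov <- GenomicRanges::coverage(GRanges(seqinfo = chromsizes))
  }
  values <- lapply(names(sl), function(ch) {
    len <- sl[[ch]]
    starts <- seq.int(1L, len, by = binWidth)
    ends <- pmin(starts + binWidth - 1L, len)
    as.numeric(IRanges::viewMeans(IRanges::Views(cov[[ch]], starts, ends)))
  })
  names(values) <- names(sl)
  SignalTrack(values, chromsizes, binWidth)
}

# per-base Rle of a track chromosome (bin value replicated over its bases)
.trackRle <- function(track, chrom) {
  len <- seqlengths(track@seqinfo)[[chrom]]
  v <- track@values[[chrom]]
  nb <- length(v)
  lens <- rep(track@binWidth, nb)
  lens[nb] <- len - (nb - 1L) * track@binWidth
  S4Vectors::Rle(v, lens)
}

#' Zero out track signal outside consensus peaks
#'
#' Bins with no overlap (>= 1 bp) to any consensus peak are set to 0; bins
#' touching a peak are kept unchanged. This mirrors restricting the signal to
#' reads falling in replicate-supported sites, removing false-positive signal
#' and background noise. Never increases any bin value.
#'
#' @param track a [SignalTrack].
#' @param peaks `GRanges`/[PeakSet]/[ConsensusPeakSet] on the same genome.
#' @return a masked [SignalTrack].
#' @export
maskToPeaks <- function(track, peaks) {
  stopifnot(is(track, "SignalTrack"))
  if (!identical(seqlengths(track@seqinfo), seqlengths(seqinfo(peaks))))
    stop("track and peaks must share chromosome sizes")
  bw <- track@binWidth
  values <- track@values
  for (ch in names(values)) {
    keep <- logical(length(values[[ch]]))
    p <- peaks[seqnames(peaks) == ch]
    if (length(p)) {
      b1 <- (start(p) - 1L) %/% bw + 1L
      b2 <- (end(p) - 1L) %/% bw + 1L
      for (i in seq_along(p)) keep[b1[i]:b2[i]] <- TRUE
    }
    values[[ch]][!keep] <- 0
  }
  SignalTrack(values, track@seqinfo, bw)
}

.tesWindow <- function(gene) {
  # 0-based TES boundary: downstream offset +k is base TES0+k on '+',
  # base TES0-k+1 on '-'
  if (as.character(strand(gene)) == "+") end(gene) else start(gene) - 1L
}

#' Strand-aware TES-flank profile matrix
#'
#' Extracts, for every gene, the binned signal over `TES - flank .. TES +
#' flank` in transcription orientation: minus-strand rows are flipped so
#' positive column offsets always point downstream of the transcript end
#' site. Column offsets are bin centers relative to the TES. The per-gene
#' summit is the leftmost bin attaining the row maximum (deterministic
#' tie-break). Genes whose window would leave the chromosome are dropped with
#' a warning.
#'
#' @param track a [SignalTrack].
#' @param genes a [GeneAnnotation].
#' @param flank flank size in bp (default 2000); must be a multiple of the
#'   track bin width.
#' @return a [TESProfileMatrix].
#' @export
tesProfile <- function(track, genes, flank = 2000L) {
  stopifnot(is(track, "SignalTrack"), is(genes, "GeneAnnotation"))
  bw <- track@binWidth
  if (flank %% bw != 0L) stop("'flank' must be a multiple of the bin width")
  g <- geneBodies(genes)
  sl <- seqlengths(track@seqinfo)
  n <- 2L * flank / bw
  offsets <- -flank + (seq_len(n) - 0.5) * bw
  rles <- lapply(names(sl), function(ch) .trackRle(track, ch))
  names(rles) <- names(sl)
  rows <- vector("list", length(g))
  ok <- logical(length(g))
  for (i in seq_along(g)) {
    ch <- as.character(seqnames(g)[i])
    plus <- as.character(strand(g)[i]) == "+"
    t0 <- .tesWindow(g[i])
    lo <- t0 - flank + 1L
    hi <- t0 + flank
    if (lo < 1L || hi > sl[[ch]]) next
    v <- as.numeric(window(rles[[ch]], lo, hi))
    if (!plus) v <- rev(v)
    rows[[i]] <- colMeans(matrix(v, nrow = bw))
    ok[i] <- TRUE
  }
  if (any(!ok))
    warning(sum(!ok), " gene(s) dropped: TES flank leaves the chromosome")
  prof <- do.call(rbind, rows[ok])
  if (is.null(prof)) prof <- matrix(numeric(0), 0, n)
  rownames(prof) <- names(g)[ok]
  summitIdx <- if (nrow(prof)) apply(prof, 1L, which.max) else integer(0)
  new("TESProfileMatrix", profile = prof, binWidth = bw,
      flank = as.integer(flank), binOffsets = offsets,
      summitOffset = offsets[summitIdx],
      summitValue = if (nrow(prof)) prof[cbind(seq_len(nrow(prof)), summitIdx)]
                    else numeric(0))
}

#' Quantile-scaled metagene profile (gene body +/- flanks)
#'
#' The gene body is rescaled to `bodyBins` equal-length segments (mean signal
#' per segment) so genes of different lengths align column-wise; flanks keep
#' native track bins. Rows are orientation-flipped for minus-strand genes.
#' Genes shorter than `bodyBins` bases, or whose flanks leave the chromosome,
#' are dropped with a warning.
#'
#' @param track a [SignalTrack].
#' @param genes a [GeneAnnotation].
#' @param bodyBins number of body segments (default 100).
#' @param flank flank in bp (default 2000), multiple of the bin width.
#' @return list with `profile` (genes x columns matrix), `mean`, `se`
#'   (per-column), and `columns` (data.frame with `zone` in
#'   upstream/body/downstream).
#' @export
metageneProfile <- function(track, genes, bodyBins = 100L, flank = 2000L) {
  stopifnot(is(track, "SignalTrack"), is(genes, "GeneAnnotation"))
  bw <- track@binWidth
  if (flank %% bw != 0L) stop("'flank' must be a multiple of the bin width")
  fb <- flank / bw
  g <- geneBodies(genes)
  sl <- seqlengths(track@seqinfo)
  rles <- lapply(names(sl), function(ch) .trackRle(track, ch))
  names(rles) <- names(sl)
  rows <- vector("list", length(g))
  ok <- logical(length(g))
  for (i in seq_along(g)) {
    ch <- as.character(seqnames(g)[i])
    plus <- as.character(strand(g)[i]) == "+"
    s <- start(g)[i]; e <- end(g)[i]
    if (e - s + 1L < bodyBins) next
    if (s - flank < 1L || e + flank > sl[[ch]]) next
    body <- as.numeric(window(rles[[ch]], s, e))
    up <- as.numeric(window(rles[[ch]], s - flank, s - 1L))
    down <- as.numeric(window(rles[[ch]], e + 1L, e + flank))
    if (!plus) {
      body <- rev(body)
      tmp <- rev(up); up <- rev(down); down <- tmp
    }
    seg <- floor(seq_along(body) * bodyBins / length(body) - 1e-9) + 1L
    bodyMeans <- as.numeric(tapply(body, factor(seg, levels = seq_len(bodyBins)),
                                   mean))
    upBins <- colMeans(matrix(up, nrow = bw))
    downBins <- colMeans(matrix(down, nrow = bw))
    rows[[i]] <- c(upBins, bodyMeans, downBins)
    ok[i] <- TRUE
  }
  if (any(!ok))
    warning(sum(!ok), " gene(s) dropped from metagene profile")
  prof <- do.call(rbind, rows[ok])
  if (is.null(prof)) prof <- matrix(numeric(0), 0, 2L * fb + bodyBins)
  rownames(prof) <- names(g)[ok]
  zone <- c(rep("upstream", fb), rep("body", bodyBins), rep("downstream", fb))
  list(profile = prof,
       mean = if (nrow(prof)) colMeans(prof) else rep(NA_real_, ncol(prof)),
       se = if (nrow(prof) > 1) apply(prof, 2L, sd) / sqrt(nrow(prof))
            else rep(0, ncol(prof)),
       columns = data.frame(column = seq_along(zone), zone = zone))
}

#' Aggregate a gene group's TES profile
#'
#' @param mat a [TESProfileMatrix].
#' @param geneIds character vector of gene ids (must all be profiled rows).
#' @return list with `mean` and `se` per bin, `n`, and `offsets`.
#' @export
aggregateGroup <- function(mat, geneIds) {
  stopifnot(is(mat, "TESProfileMatrix"))
  if (!length(geneIds)) stop("empty gene group")
  missing <- setdiff(geneIds, rownames(mat@profile))
  if (length(missing))
    stop("gene ids not in profile: ", paste(head(missing, 3), collapse = ", "))
  sub <- mat@profile[geneIds, , drop = FALSE]
  list(mean = colMeans(sub),
       se = if (nrow(sub) > 1) apply(sub, 2L, sd) / sqrt(nrow(sub))
            else rep(0, ncol(sub)),
       n = nrow(sub), offsets = mat@binOffsets)
}

#' Classify genes by TES-flank summit position
#'
#' A gene joins the group whose window `[center - tolerance, center +
#' tolerance]` contains its summit offset, provided the summit is downstream
#' of the TES (offset > 0) and passes the minimum-summit rule; otherwise it
#' is `NONE`. Windows must be disjoint.
#'
#' The minimum-summit rule, in order of precedence: an absolute `minSummit`
#' value; a cohort quantile of per-gene summit values (`minSummitQuantile`);
#' or the default per-gene prominence rule, requiring the summit to reach
#' `minSummitRatio` times the gene's own row median (summit > 0 when the
#' median is 0). The prominence rule is scale-free and does not depend on how
#' many genes in the cohort carry a flank bump.
#'
#' @param mat a [TESProfileMatrix].
#' @param centers downstream window centers in bp (default `c(500, 1000)`).
#' @param tolerance half-width of each window in bp (default 250).
#' @param minSummit absolute minimum summit value, or `NULL`.
#' @param minSummitQuantile cohort quantile in \[0,1\] for the threshold, or
#'   `NULL`.
#' @param minSummitRatio prominence ratio for the default rule (default 3).
#' @return data.frame with `gene_id`, `group` (factor with levels
#'   `TES_PLUS_<center>` and `NONE`), `summit_offset`, `summit_value`;
#'   parameters recorded in `attr(, "params")`.
#' @export
classifyTesFlank <- function(mat, centers = c(500, 1000), tolerance = 250,
                             minSummit = NULL, minSummitQuantile = NULL,
                             minSummitRatio = 3) {
  stopifnot(is(mat, "TESProfileMatrix"))
  centers <- sort(centers)
  if (any(centers <= 0) || any(centers > mat@flank))
    stop("window centers must be positive and within the flank")
  if (length(centers) > 1 && min(diff(centers)) < 2 * tolerance)
    stop("classification windows overlap: tolerance too large for centers")
  off <- mat@summitOffset
  val <- mat@summitValue
  pass <- if (!is.null(minSummit)) {
    val >= minSummit
  } else if (!is.null(minSummitQuantile)) {
    val >= quantile(val, minSummitQuantile, names = FALSE)
  } else {
    rowMed <- apply(mat@profile, 1L, median)
    ifelse(rowMed > 0, val >= minSummitRatio * rowMed, val > 0)
  }
  lv <- c(paste0("TES_PLUS_", centers), "NONE")
  group <- rep("NONE", nrow(mat@profile))
  for (k in seq_along(centers)) {
    # first-match: a summit on a shared window edge goes to the lower center
    inWin <- off > 0 & abs(off - centers[k]) <= tolerance & pass &
      group == "NONE"
    group[inWin] <- paste0("TES_PLUS_", centers[k])
  }
  out <- data.frame(gene_id = rownames(mat@profile),
                    group = factor(group, levels = lv),
                    summit_offset = off, summit_value = val,
                    stringsAsFactors = FALSE)
  attr(out, "params") <- list(centers = centers, tolerance = tolerance,
                              minSummit = minSummit,
                              minSummitQuantile = minSummitQuantile,
                              minSummitRatio = minSummitRatio)
  out
}
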