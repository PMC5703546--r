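#' Build genomic partition footprints from gene models
#'
#' Promoters are strand-aware windows `[TSS - promoterUp, TSS + promoterDown)`
#' (defaults 2000/500 bp), clamped at chromosome edges. Coding-exon and
#' intron footprints are taken per gene and *not* complemented against each
#' other — a nested gene's exon may sit inside another gene's intron and both
#' categories then cover the same bases. First introns are defined in
#' transcription order (strand-aware); `intergenic` is the genome complement
#' of merged gene bodies plus promoters.
#'
#' @param genes a [GeneAnnotation].
#' @param chromsizes a `Seqinfo` (defaults to the annotation's).
#' @param promoterUp,promoterDown promoter window in bp upstream/downstream
#'   of the TSS.
#' @return a [PartitionMap].
#' @export
buildPartitions <- function(genes, chromsizes = NULL,
                            promoterUp = 2000L, promoterDown = 500L) {
  stopifnot(is(genes, "GeneAnnotation"))
  if (promoterUp < 0 || promoterDown < 0)
    stop("promoter window sizes must be >= 0")
  g <- geneBodies(genes)
  if (is.null(chromsizes)) chromsizes <- seqinfo(g)
  si <- chromsizes
  prom <- trim(suppressWarnings(
    promoters(g, upstream = promoterUp, downstream = promoterDown)))
  prom <- prom[width(prom) > 0L]
  exons <- geneExons(genes)
  exonFlat <- unlist(exons, use.names = FALSE)
  introns <- psetdiff(g, exons)
  nInt <- lengths(introns)
  intronFlat <- unlist(introns, use.names = FALSE)
  # transcription-order first intron: genomic-leftmost on '+', rightmost on '-'
  firstIdx <- logical(length(intronFlat))
  if (length(intronFlat)) {
    offsets <- cumsum(c(0L, head(nInt, -1L)))
    plus <- as.character(strand(g)) == "+"
    pick <- ifelse(nInt > 0L, offsets + ifelse(plus, 1L, nInt), NA_integer_)
    firstIdx[pick[!is.na(pick)]] <- TRUE
  }
  bodiesProm <- GenomicRanges::reduce(
    c(granges(g), granges(prom)), ignore.strand = TRUE)
  interg <- gaps(bodiesProm)
  interg <- interg[strand(interg) == "*"]
  cats <- list(
    promoter = sort(granges(prom), ignore.strand = TRUE),
    coding_exon = sort(granges(exonFlat), ignore.strand = TRUE),
    intron_all = sort(granges(intronFlat), ignore.strand = TRUE),
    intron_first = sort(granges(intronFlat[firstIdx]), ignore.strand = TRUE),
    intron_later = sort(granges(intronFlat[!firstIdx]), ignore.strand = TRUE),
    intergenic = sort(granges(interg), ignore.strand = TRUE)
  )
  cats <- lapply(cats, function(x) { strand(x) <- "*"; x })
  new("PartitionMap", categories = cats,
      promoterUp = as.integer(promoterUp),
      promoterDown = as.integer(promoterDown))
}

#' Classify peaks against genomic partitions
#'
#' A peak is counted in *every* category it overlaps by >= 1 bp
#' (non-mutually-exclusive counting: larger sites spanning several partitions
#' are tabulated several times), so per-category counts can sum to more than
#' the number of peaks.
#'
#' @param peaks `GRanges`/[PeakSet].
#' @param parts a [PartitionMap].
#' @return list with `counts` (named integer), `fractions` (counts / number
#'   of peaks), `flags` (logical peaks x categories matrix) and `total`.
#' @export
classifyPeaks <- function(peaks, parts) {
  stopifnot(is(parts, "PartitionMap"))
  flags <- overlapMembership(peaks, parts@categories)
  counts <- setNames(as.integer(colSums(flags)), colnames(flags))
  total <- length(peaks)
  list(counts = counts,
       fractions = if (total > 0) counts / total else counts * NA_real_,
       flags = flags, total = total)
}

#' Per-category peak length summaries
#'
#' Lengths are `end - start` in bp; a peak contributes its length to every
#' category it overlaps. Empty categories are flagged (`n = 0`, NA summaries)
#' rather than raising.
#'
#' @param peaks `GRanges`/[PeakSet].
#' @param parts a [PartitionMap], or `NULL` for a single overall summary.
#' @return data.frame with columns `category, n, min, q25, median, mean, q75,
#'   max`.
#' @export
lengthDistribution <- function(peaks, parts = NULL) {
  w <- width(peaks)
  summarise <- function(len) {
    if (!length(len))
      return(c(n = 0, min = NA, q25 = NA, median = NA, mean = NA, q75 = NA,
               max = NA))
    q <- quantile(len, c(0.25, 0.5, 0.75), names = FALSE)
    c(n = length(len), min = min(len), q25 = q[1], median = q[2],
      mean = mean(len), q75 = q[3], max = max(len))
  }
  if (is.null(parts)) {
    out <- data.frame(category = "all", t(summarise(w)))
  } else {
    flags <- overlapMembership(peaks, parts@categories)
    out <- do.call(rbind, lapply(colnames(flags), function(cat) {
      data.frame(category = cat, t(summarise(w[flags[, cat]])))
    }))
  }
  rownames(out) <- NULL
  out
}
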