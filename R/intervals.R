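#' Do two intervals overlap?
#'
#' Half-open semantics on the underlying BED coordinates: at least 1 shared
#' base is required, so book-ended intervals do not overlap. Strand is
#' ignored.
#'
#' @param a,b `GRanges` of length 1 (or equal length for vectorized use).
#' @param minOverlap minimum shared bases (default 1).
#' @return logical vector.
#' @export
intervalsOverlap <- function(a, b, minOverlap = 1L) {
  stopifnot(length(a) == length(b))
  same <- as.character(seqnames(a)) == as.character(seqnames(b))
  ov <- pmin(end(a), end(b)) - pmax(start(a), start(b)) + 1L
  same & ov >= minOverlap
}

#' Merge intervals by single linkage
#'
#' Intervals whose gap is at most `gap` bp collapse into one spanning
#' interval. At `gap = 0` overlapping *and* book-ended intervals merge (a
#' single site split by a caller boundary counts once); output is sorted and
#' pairwise non-overlapping. `mergePeaks` is idempotent.
#'
#' @param peaks a [PeakSet] or `GRanges`.
#' @param gap maximum gap in bp (>= 0) for merging; default 0.
#' @return a merged object of the same class (label preserved).
#' @export
mergePeaks <- function(peaks, gap = 0L) {
  if (length(gap) != 1L || is.na(gap) || gap < 0)
    stop("'gap' must be a single non-negative integer")
  red <- GenomicRanges::reduce(granges(peaks), min.gapwidth = gap + 1L,
                               ignore.strand = TRUE)
  if (is(peaks, "PeakSet")) PeakSet(red, label = peaks@label) else sort(red)
}

#' Overlap membership of query regions across subject sets
#'
#' For each query interval, reports a logical vector over `subjects`: entry
#' `j` is `TRUE` iff the query overlaps (>= `minOverlap` shared bp) at least
#' one interval of `subjects[[j]]`. This is the kernel behind Venn membership
#' and differential site calls.
#'
#' @param query a `GRanges`/[PeakSet].
#' @param subjects named list of `GRanges`/[PeakSet].
#' @param minOverlap minimum shared bases (default 1).
#' @return logical matrix, `length(query)` rows x `length(subjects)` columns.
#' @export
overlapMembership <- function(query, subjects, minOverlap = 1L) {
  stopifnot(is.list(subjects) || is(subjects, "List"))
  if (!length(query)) {
    m <- matrix(logical(0), nrow = 0, ncol = length(subjects))
    colnames(m) <- names(subjects)
    return(m)
  }
  m <- vapply(subjects, function(s) {
    overlapsAny(granges(query), granges(s), minoverlap = minOverlap,
                ignore.strand = TRUE)
  }, logical(length(query)))
  m <- matrix(m, nrow = length(query), ncol = length(subjects))
  colnames(m) <- names(subjects)
  m
}

#' Total bases covered by a set of intervals
#'
#' @param peaks `GRanges`/[PeakSet].
#' @return integer base count of the merged footprint.
#' @export
coveredBases <- function(peaks) {
  sum(width(GenomicRanges::reduce(granges(peaks), ignore.strand = TRUE)))
}
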