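#' Replicate-consensus ("common") peaks for one stage
#'
#' Peaks present in only one biological replicate are treated as
#' false-positive calls and discarded. Concretely: form the connected
#' components of mutually overlapping rep1/rep2 intervals (>= 1 shared bp;
#' book-ends do not connect) and, for every component containing at least one
#' interval from each replicate, emit the merged span of the component.
#'
#' @param rep1,rep2 [PeakSet]s on the same genome.
#' @param stage stage identifier for the result.
#' @return a [ConsensusPeakSet].
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chr1", 10000)
#' r1 <- PeakSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300)),
#'               "s_rep1", si)
#' r2 <- PeakSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(251, 400)),
#'               "s_rep2", si)
#' replicateConsensus(r1, r2, stage = "s")  # one site spanning 101..400
#' @export
replicateConsensus <- function(rep1, rep2, stage = "stage") {
  stopifnot(is(rep1, "PeakSet"), is(rep2, "PeakSet"))
  if (!identical(seqlengths(rep1), seqlengths(rep2)))
    stop("replicates must share the same chromosome sizes")
  if (!length(rep1) || !length(rep2))
    warning("empty replicate peak set: consensus for stage '", stage,
            "' is empty")
  combined <- c(granges(rep1), granges(rep2))
  # min.gapwidth = 0: only genuinely overlapping intervals form a component
  comp <- GenomicRanges::reduce(combined, min.gapwidth = 0L,
                                ignore.strand = TRUE)
  keep <- overlapsAny(comp, granges(rep1), ignore.strand = TRUE) &
    overlapsAny(comp, granges(rep2), ignore.strand = TRUE)
  new("ConsensusPeakSet", PeakSet(comp[keep], label = stage), stage = stage)
}

.patternName <- function(membership, setNames) {
  if (!nrow(membership)) return(character(0))
  apply(membership, 1L, function(row) paste(setNames[row], collapse = "&"))
}

#' Venn membership of merged-union regions across stages
#'
#' The "unique site" universe is the merged union (gap = 0, book-ends merge)
#' of all stage consensus sets; each universe region is flagged for every
#' stage it overlaps. Pattern counts partition the universe.
#'
#' @param stages named list of [ConsensusPeakSet] (>= 2); names default to
#'   each set's stage.
#' @return a [VennReport].
#' @export
stageVenn <- function(stages) {
  if (length(stages) < 2L) stop("need >= 2 stage sets")
  if (is.null(names(stages)))
    names(stages) <- vapply(stages, function(s)
      if (is(s, "ConsensusPeakSet")) s@stage else NA_character_, character(1))
  if (anyNA(names(stages)) || anyDuplicated(names(stages)))
    stop("stage sets must have unique names")
  universe <- GenomicRanges::reduce(
    do.call(c, unname(lapply(stages, granges))), min.gapwidth = 1L,
    ignore.strand = TRUE)
  membership <- overlapMembership(universe, stages)
  patterns <- .patternName(membership, names(stages))
  counts <- table(patterns)
  new("VennReport", universe = universe, membership = membership,
      counts = setNames(as.integer(counts), names(counts)))
}

#' Differential (gained / lost) sites between two stages
#'
#' Lost sites are `from`-stage consensus intervals with no overlap in the
#' `to` stage; gained sites the converse. Counts satisfy
#' `n_lost + n_shared_from = |from|` and `n_gained + n_shared_to = |to|`.
#' The loss/gain ratio is `NA` (flagged undefined, not an error) when nothing
#' is gained.
#'
#' @param fromStage,toStage [ConsensusPeakSet]s.
#' @return a [StageComparison].
#' @export
differentialSites <- function(fromStage, toStage) {
  stopifnot(is(fromStage, "ConsensusPeakSet"), is(toStage, "ConsensusPeakSet"))
  lostIdx <- !overlapsAny(granges(fromStage), granges(toStage),
                          ignore.strand = TRUE)
  gainIdx <- !overlapsAny(granges(toStage), granges(fromStage),
                          ignore.strand = TRUE)
  nLost <- sum(lostIdx); nGained <- sum(gainIdx)
  new("StageComparison",
      fromStage = fromStage@stage, toStage = toStage@stage,
      nLost = as.integer(nLost), nGained = as.integer(nGained),
      nSharedFrom = as.integer(length(fromStage) - nLost),
      nSharedTo = as.integer(length(toStage) - nGained),
      lossGainRatio = if (nGained > 0) nLost / nGained else NA_real_,
      lost = granges(fromStage)[lostIdx],
      gained = granges(toStage)[gainIdx])
}

#' Percentage of a whole, rounded half-up to one decimal
#'
#' @param part,whole non-negative counts; `whole` must be positive.
#' @return `100 * part / whole` rounded half-up to 1 decimal.
#' @examples
#' percentOf(13525, 49960)  # 27.1
#' @export
percentOf <- function(part, whole) {
  if (any(whole <= 0)) stop("'whole' must be positive")
  if (any(part < 0)) stop("'part' must be non-negative")
  x <- 100 * part / whole
  # half-up, guarded against representation error just below a .5 boundary
  floor(x * 10 + 0.5 + sqrt(.Machine$double.eps)) / 10
}
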