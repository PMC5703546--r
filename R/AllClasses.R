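#' @import methods
#' @import BiocGenerics
#' @import S4Vectors
#' @import IRanges
#' @import GenomicRanges
#' @importFrom GenomeInfoDb Seqinfo seqinfo seqlengths seqnames seqlevels
#'   genome keepSeqlevels
#' @importFrom stats rlnorm runif rnorm setNames
#' @importFrom utils read.table write.table
NULL

#' PeakSet: a sorted set of genomic peaks under a governing genome
#'
#' A `PeakSet` is a [GenomicRanges::GRanges] subclass holding peak calls
#' (e.g., DNase hypersensitive sites or TF ChIP peaks). Invariants enforced by
#' the validity method: intervals are sorted by (chromosome, start, end),
#' every width is >= 1 bp, every chromosome has a known length in the
#' attached `Seqinfo`, and no interval extends beyond its chromosome.
#' Coordinates are stored 1-based closed (GRanges convention); BED I/O
#' converts from/to 0-based half-open at the boundary.
#'
#' @slot label single string identifying the set (e.g. `"d0_rep1"`).
#' @export
setClass("PeakSet",
  contains = "GRanges",
  representation(label = "character"),
  prototype(label = NA_character_)
)

setValidity("PeakSet", function(object) {
  msg <- character()
  if (length(object@label) != 1L)
    msg <- c(msg, "'label' must be a single string")
  if (length(object)) {
    sl <- seqlengths(object)
    if (anyNA(sl))
      msg <- c(msg, "all chromosomes must have a known length (Seqinfo)")
    if (any(width(object) < 1L))
      msg <- c(msg, "all intervals must have width >= 1 bp")
    if (!anyNA(sl) && any(end(object) > sl[as.character(seqnames(object))]))
      msg <- c(msg, "interval end exceeds chromosome length")
    if (is.unsorted(order(as.integer(seqnames(object)), start(object), end(object))))
      msg <- c(msg, "intervals must be sorted by (chrom, start, end)")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakSet
#'
#' Sorts the input ranges, drops strand (peak-vs-peak operations are
#' unstranded) and validates against the governing genome.
#'
#' @param gr a `GRanges` (its `seqinfo` must carry chromosome lengths, or pass
#'   `seqinfo`).
#' @param label identifier for the set.
#' @param seqinfo optional `Seqinfo` to impose on `gr`.
#' @return a `PeakSet`.
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chr1", 1000)
#' ps <- PeakSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 100)),
#'               label = "demo", seqinfo = si)
#' @export
PeakSet <- function(gr, label = NA_character_, seqinfo = NULL) {
  if (!is(gr, "GRanges")) stop("'gr' must be a GRanges")
  if (!is.null(seqinfo)) {
    gr2 <- GRanges(seqnames(gr), ranges(gr), strand = "*", seqinfo = seqinfo)
    mcols(gr2) <- mcols(gr)
    gr <- gr2
  } else {
    strand(gr) <- "*"
  }
  o <- order(as.integer(seqnames(gr)), start(gr), end(gr))
  gr <- gr[o]
  new("PeakSet", gr, label = as.character(label))
}

#' ConsensusPeakSet: replicate-supported peaks of one stage
#'
#' A [PeakSet] whose every interval is the merged span of a connected
#' component of overlapping peak calls containing at least one call from each
#' of two biological replicates.
#'
#' @slot stage stage identifier (e.g. `"d0"`).
#' @export
setClass("ConsensusPeakSet",
  contains = "PeakSet",
  representation(stage = "character"),
  prototype(stage = NA_character_)
)

#' GeneAnnotation: collapsed gene models
#'
#' Holds one model per gene: the gene body as a stranded `GRanges` (names =
#' gene ids) and the exons as a parallel `GRangesList` in genomic order.
#' Transcription-order quantities (TSS, TES, first intron) are derived
#' strand-awarely by the accessors.
#'
#' @slot genes stranded `GRanges` of gene bodies, names are gene ids.
#' @slot exons `GRangesList` parallel to `genes`.
#' @export
setClass("GeneAnnotation",
  representation(genes = "GRanges", exons = "GRangesList")
)

setValidity("GeneAnnotation", function(object) {
  msg <- character()
  g <- object@genes
  if (is.null(names(g)) || anyDuplicated(names(g)))
    msg <- c(msg, "gene ids (names of 'genes') must be present and unique")
  if (length(g) != length(object@exons))
    msg <- c(msg, "'exons' must be parallel to 'genes'")
  if (length(g) && !all(strand(g) %in% c("+", "-")))
    msg <- c(msg, "gene strand must be '+' or '-'")
  if (length(g)) {
    within <- all(unlist(start(object@exons)) >= rep(start(g), lengths(object@exons))) &&
      all(unlist(end(object@exons)) <= rep(end(g), lengths(object@exons)))
    if (!within) msg <- c(msg, "exons must lie within their gene span")
  }
  if (length(msg)) msg else TRUE
})

#' SignalTrack: fixed-bin genome-wide coverage
#'
#' Per-chromosome numeric vectors of normalized coverage over fixed bins of
#' `binWidth` bp. Vector `i` has length `ceiling(chromLength/binWidth)`; all
#' values are finite and >= 0. The last (partial) bin averages only in-genome
#' bases.
#'
#' @slot values named list of numeric vectors, one per chromosome.
#' @slot binWidth bin width in bp.
#' @slot seqinfo governing `Seqinfo`.
#' @export
setClass("SignalTrack",
  representation(values = "list", binWidth = "integer", seqinfo = "Seqinfo")
)

setValidity("SignalTrack", function(object) {
  msg <- character()
  sl <- seqlengths(object@seqinfo)
  if (length(object@binWidth) != 1L || object@binWidth < 1L)
    msg <- c(msg, "'binWidth' must be a single positive integer")
  if (!identical(sort(names(object@values)), sort(names(sl))))
    msg <- c(msg, "'values' must have one vector per chromosome of the Seqinfo")
  else {
    nb <- ceiling(sl / as.numeric(object@binWidth))
    ok <- vapply(names(sl), function(ch) {
      v <- object@values[[ch]]
      length(v) == nb[[ch]] && all(is.finite(v)) && all(v >= 0)
    }, logical(1))
    if (!all(ok))
      msg <- c(msg, "each vector must have ceiling(len/binWidth) finite non-negative values")
  }
  if (length(msg)) msg else TRUE
})

#' TESProfileMatrix: per-gene binned signal around transcript end sites
#'
#' Rows are genes, columns are bins spanning TES-flank .. TES+flank in
#' transcription orientation (minus-strand rows are flipped so positive
#' offsets always point downstream of the TES). `binOffsets` gives each
#' column's bin-center offset from the TES in bp; the summit is the leftmost
#' column attaining the row maximum.
#'
#' @slot profile numeric matrix, rownames = gene ids.
#' @slot binWidth bin width in bp.
#' @slot flank flank size in bp.
#' @slot binOffsets numeric vector of column bin-center offsets (bp).
#' @slot summitOffset per-gene summit offset from the TES (bp).
#' @slot summitValue per-gene summit signal value.
#' @export
setClass("TESProfileMatrix",
  representation(profile = "matrix", binWidth = "integer", flank = "integer",
                 binOffsets = "numeric", summitOffset = "numeric",
                 summitValue = "numeric")
)

setValidity("TESProfileMatrix", function(object) {
  msg <- character()
  if (ncol(object@profile) != 2L * object@flank / object@binWidth)
    msg <- c(msg, "ncol(profile) must equal 2*flank/binWidth")
  if (length(object@binOffsets) != ncol(object@profile))
    msg <- c(msg, "'binOffsets' must be parallel to profile columns")
  if (length(object@summitOffset) != nrow(object@profile) ||
      length(object@summitValue) != nrow(object@profile))
    msg <- c(msg, "summit vectors must be parallel to profile rows")
  if (is.null(rownames(object@profile)))
    msg <- c(msg, "profile rows must be named by gene id")
  if (length(msg)) msg else TRUE
})

#' PartitionMap: genomic partition footprints
#'
#' Named `GRanges` footprints for the six genomic categories used to classify
#' DHS sites: `promoter`, `coding_exon`, `intron_all`, `intron_first`,
#' `intron_later`, `intergenic`. Categories are *not* mutually exclusive
#' (a base may belong to several genes' categories); only `intergenic` is the
#' genome complement of merged gene bodies plus promoters. Invariant:
#' `intron_first` and `intron_later` together cover `intron_all`.
#'
#' @slot categories named list of `GRanges`.
#' @slot promoterUp,promoterDown promoter window half-widths in bp.
#' @export
setClass("PartitionMap",
  representation(categories = "list", promoterUp = "integer",
                 promoterDown = "integer")
)

.partitionNames <- c("promoter", "coding_exon", "intron_all", "intron_first",
                     "intron_later", "intergenic")

setValidity("PartitionMap", function(object) {
  msg <- character()
  if (!identical(names(object@categories), .partitionNames))
    msg <- c(msg, paste("categories must be exactly:",
                        paste(.partitionNames, collapse = ", ")))
  else {
    firstLater <- GenomicRanges::reduce(
      c(object@categories$intron_first, object@categories$intron_later),
      ignore.strand = TRUE)
    allIn <- GenomicRanges::reduce(object@categories$intron_all,
                                   ignore.strand = TRUE)
    if (!identical(ranges(sort(firstLater)), ranges(sort(allIn))))
      msg <- c(msg, "intron_first U intron_later must equal intron_all")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname PartitionMap-class
#' @param x a `PartitionMap`.
#' @export
partitionCategories <- function(x) {
  stopifnot(is(x, "PartitionMap"))
  x@categories
}

#' VennReport: merged-union membership across peak sets
#'
#' The region universe is the merged union (gap = 0, book-ends merge) of all
#' input sets; `membership[i, j]` says whether universe region `i` overlaps
#' any interval of input set `j`. Pattern counts partition the universe and no
#' region carries the all-false pattern.
#'
#' @slot universe `GRanges` of merged-union regions.
#' @slot membership logical matrix (regions x sets).
#' @slot counts named integer vector of per-pattern tallies (names like
#'   `"d0&d9"`).
#' @export
setClass("VennReport",
  representation(universe = "GRanges", membership = "matrix", counts = "integer")
)

setValidity("VennReport", function(object) {
  msg <- character()
  if (nrow(object@membership) != length(object@universe))
    msg <- c(msg, "membership rows must be parallel to the universe")
  if (nrow(object@membership) && !all(rowSums(object@membership) >= 1L))
    msg <- c(msg, "no universe region may have the all-false pattern")
  if (sum(object@counts) != length(object@universe))
    msg <- c(msg, "pattern counts must sum to the universe size")
  if (length(msg)) msg else TRUE
})

#' StageComparison: gained/lost sites between two stages
#'
#' @slot fromStage,toStage stage identifiers.
#' @slot nLost,nGained,nSharedFrom,nSharedTo counts.
#' @slot lossGainRatio `nLost/nGained`; `NA` (flagged, not an error) when
#'   `nGained == 0`.
#' @slot lost,gained the differential regions as `GRanges`.
#' @export
setClass("StageComparison",
  representation(fromStage = "character", toStage = "character",
                 nLost = "integer", nGained = "integer",
                 nSharedFrom = "integer", nSharedTo = "integer",
                 lossGainRatio = "numeric", lost = "GRanges", gained = "GRanges")
)

#' RegulomeOverlapReport: DHS x RUNX2 x CTCF co-occupancy for one stage
#'
#' DHS-side counts follow Venn semantics (a site with both factors counts
#' once under `both`); TF-side fractions report the share of TF peaks that
#' overlap at least one DHS.
#'
#' @slot stage stage identifier.
#' @slot counts named integer vector: `dhs_total`, `with_runx2_only`,
#'   `with_ctcf_only`, `with_both`, `with_neither`.
#' @slot fractions named numeric vector: `with_either`, `runx2_in_dhs`,
#'   `ctcf_in_dhs`, `runx2_outside_dhs`, `ctcf_outside_dhs`.
#' @export
setClass("RegulomeOverlapReport",
  representation(stage = "character", counts = "integer", fractions = "numeric")
)

setValidity("RegulomeOverlapReport", function(object) {
  msg <- character()
  cn <- c("dhs_total", "with_runx2_only", "with_ctcf_only", "with_both",
          "with_neither")
  if (!all(cn %in% names(object@counts)))
    msg <- c(msg, "missing count fields")
  else if (sum(object@counts[cn[-1]]) != object@counts[["dhs_total"]])
    msg <- c(msg, "DHS-side counts must partition dhs_total")
  fr <- object@fractions
  if (length(fr) && any(fr < 0 | fr > 1, na.rm = TRUE))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
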