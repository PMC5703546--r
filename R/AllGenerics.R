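#' @rdname PeakSet-class
#' @param object,x an object.
#' @export
setGeneric("peakLabel", function(x) standardGeneric("peakLabel"))

#' @rdname PeakSet-class
#' @export
setMethod("peakLabel", "PeakSet", function(x) x@label)

#' @rdname ConsensusPeakSet-class
#' @param x a `ConsensusPeakSet`.
#' @export
setGeneric("stageName", function(x) standardGeneric("stageName"))

#' @rdname ConsensusPeakSet-class
#' @export
setMethod("stageName", "ConsensusPeakSet", function(x) x@stage)

#' @rdname GeneAnnotation-class
#' @param x a `GeneAnnotation` (or, for `tss`/`tes`, any object with a
#'   method).
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname GeneAnnotation-class
#' @export
setMethod("geneIds", "GeneAnnotation", function(x) names(x@genes))

#' @rdname GeneAnnotation-class
#' @export
setGeneric("geneBodies", function(x) standardGeneric("geneBodies"))

#' @rdname GeneAnnotation-class
#' @export
setMethod("geneBodies", "GeneAnnotation", function(x) x@genes)

#' @rdname GeneAnnotation-class
#' @export
setGeneric("geneExons", function(x) standardGeneric("geneExons"))

#' @rdname GeneAnnotation-class
#' @export
setMethod("geneExons", "GeneAnnotation", function(x) x@exons)

#' Transcription start / end sites
#'
#' Strand-aware 1-based positions: on `+` the TSS is the gene start and the
#' TES the gene end; on `-` the reverse.
#'
#' @param x a `GeneAnnotation`.
#' @return named integer vector of positions.
#' @export
setGeneric("tss", function(x) standardGeneric("tss"))

#' @rdname tss
#' @export
setMethod("tss", "GeneAnnotation", function(x) {
  g <- x@genes
  setNames(ifelse(as.character(strand(g)) == "+", start(g), end(g)), names(g))
})

#' @rdname tss
#' @export
setGeneric("tes", function(x) standardGeneric("tes"))

#' @rdname tss
#' @export
setMethod("tes", "GeneAnnotation", function(x) {
  g <- x@genes
  setNames(ifelse(as.character(strand(g)) == "+", end(g), start(g)), names(g))
})

#' @rdname GeneAnnotation-class
#' @export
setMethod("length", "GeneAnnotation", function(x) length(x@genes))

#' @rdname SignalTrack-class
#' @param x a `SignalTrack` or `TESProfileMatrix`.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname SignalTrack-class
#' @export
setMethod("binWidth", "SignalTrack", function(x) x@binWidth)

#' @rdname TESProfileMatrix-class
#' @export
setMethod("binWidth", "TESProfileMatrix", function(x) x@binWidth)

#' @rdname SignalTrack-class
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname SignalTrack-class
#' @export
setMethod("trackValues", "SignalTrack", function(x) x@values)

#' @rdname SignalTrack-class
#' @export
setMethod("seqinfo", "SignalTrack", function(x) x@seqinfo)

#' @rdname TESProfileMatrix-class
#' @param x a `TESProfileMatrix`.
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @rdname TESProfileMatrix-class
#' @export
setMethod("profileMatrix", "TESProfileMatrix", function(x) x@profile)

#' @rdname TESProfileMatrix-class
#' @export
setGeneric("binOffsets", function(x) standardGeneric("binOffsets"))

#' @rdname TESProfileMatrix-class
#' @export
setMethod("binOffsets", "TESProfileMatrix", function(x) x@binOffsets)

#' @rdname TESProfileMatrix-class
#' @export
setGeneric("summitOffsets", function(x) standardGeneric("summitOffsets"))

#' @rdname TESProfileMatrix-class
#' @export
setMethod("summitOffsets", "TESProfileMatrix",
          function(x) setNames(x@summitOffset, rownames(x@profile)))

#' @rdname TESProfileMatrix-class
#' @export
setGeneric("summitValues", function(x) standardGeneric("summitValues"))

#' @rdname TESProfileMatrix-class
#' @export
setMethod("summitValues", "TESProfileMatrix",
          function(x) setNames(x@summitValue, rownames(x@profile)))

#' @rdname VennReport-class
#' @param x a `VennReport`.
#' @export
setGeneric("vennCounts", function(x) standardGeneric("vennCounts"))

#' @rdname VennReport-class
#' @export
setMethod("vennCounts", "VennReport", function(x) x@counts)

#' @rdname VennReport-class
#' @export
setGeneric("vennUniverse", function(x) standardGeneric("vennUniverse"))

#' @rdname VennReport-class
#' @export
setMethod("vennUniverse", "VennReport", function(x) x@universe)

#' @rdname VennReport-class
#' @export
setGeneric("vennMembership", function(x) standardGeneric("vennMembership"))

#' @rdname VennReport-class
#' @export
setMethod("vennMembership", "VennReport", function(x) x@membership)

#' @rdname StageComparison-class
#' @param x a `StageComparison`.
#' @export
setGeneric("comparisonCounts", function(x) standardGeneric("comparisonCounts"))

#' @rdname StageComparison-class
#' @export
setMethod("comparisonCounts", "StageComparison", function(x) {
  c(n_lost = x@nLost, n_gained = x@nGained,
    n_shared_from = x@nSharedFrom, n_shared_to = x@nSharedTo)
})

#' @rdname StageComparison-class
#' @export
setGeneric("lossGainRatio", function(x) standardGeneric("lossGainRatio"))

#' @rdname StageComparison-class
#' @export
setMethod("lossGainRatio", "StageComparison", function(x) x@lossGainRatio)

#' @rdname StageComparison-class
#' @export
setGeneric("lostSites", function(x) standardGeneric("lostSites"))

#' @rdname StageComparison-class
#' @export
setMethod("lostSites", "StageComparison", function(x) x@lost)

#' @rdname StageComparison-class
#' @export
setGeneric("gainedSites", function(x) standardGeneric("gainedSites"))

#' @rdname StageComparison-class
#' @export
setMethod("gainedSites", "StageComparison", function(x) x@gained)

#' @rdname RegulomeOverlapReport-class
#' @param x a `RegulomeOverlapReport`.
#' @export
setGeneric("overlapCounts", function(x) standardGeneric("overlapCounts"))

#' @rdname RegulomeOverlapReport-class
#' @export
setMethod("overlapCounts", "RegulomeOverlapReport", function(x) x@counts)

#' @rdname RegulomeOverlapReport-class
#' @export
setGeneric("overlapFractions", function(x) standardGeneric("overlapFractions"))

#' @rdname RegulomeOverlapReport-class
#' @export
setMethod("overlapFractions", "RegulomeOverlapReport", function(x) x@fractions)

setMethod("show", "PeakSet", function(object) {
  cat("PeakSet '", object@label, "' with ", length(object), " intervals\n",
      sep = "")
  callNextMethod()
})

setMethod("show", "ConsensusPeakSet", function(object) {
  cat("ConsensusPeakSet for stage '", object@stage, "' with ",
      length(object), " consensus sites\n", sep = "")
})

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation with", length(object@genes), "gene models on",
      length(seqlevels(object@genes)), "chromosome(s)\n")
})

setMethod("show", "SignalTrack", function(object) {
  cat("SignalTrack:", length(object@values), "chromosome(s), bin width",
      object@binWidth, "bp\n")
})

setMethod("show", "TESProfileMatrix", function(object) {
  cat("TESProfileMatrix:", nrow(object@profile), "genes x",
      ncol(object@profile), "bins (TES +/-", object@flank, "bp, bin",
      object@binWidth, "bp)\n")
})

setMethod("show", "VennReport", function(object) {
  cat("VennReport over", length(object@universe), "merged-union regions:\n")
  print(object@counts)
})

setMethod("show", "StageComparison", function(object) {
  cat("StageComparison ", object@fromStage, " -> ", object@toStage,
      ": lost ", object@nLost, ", gained ", object@nGained,
      ", loss/gain ", format(object@lossGainRatio, digits = 4), "\n", sep = "")
})

setMethod("show", "RegulomeOverlapReport", function(object) {
  cat("RegulomeOverlapReport for stage '", object@stage, "'\n", sep = "")
  print(object@counts)
  print(round(object@fractions, 4))
})
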