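#' DHS x RUNX2 x CTCF co-occupancy for one stage
#'
#' DHS-side counting follows Venn semantics: each consensus DHS site is
#' flagged once as runx2-only, ctcf-only, both, or neither, regardless of how
#' many TF peaks hit it. TF-side fractions are reported as well because both
#' directions are informative (a TF peak may sit outside any DHS).
#'
#' @param dhs a [ConsensusPeakSet].
#' @param runx2,ctcf [PeakSet]s of TF ChIP peaks (either may be empty; a
#'   warning is issued and the corresponding fractions are 0).
#' @param minOverlap minimum shared bases for an overlap (default 1).
#' @return a [RegulomeOverlapReport].
#' @export
regulomeOverlap <- function(dhs, runx2, ctcf, minOverlap = 1L) {
  stopifnot(is(dhs, "ConsensusPeakSet"))
  if (!length(runx2)) warning("empty RUNX2 peak set")
  if (!length(ctcf)) warning("empty CTCF peak set")
  m <- overlapMembership(dhs, list(runx2 = runx2, ctcf = ctcf),
                         minOverlap = minOverlap)
  nBoth <- sum(m[, "runx2"] & m[, "ctcf"])
  nR <- sum(m[, "runx2"] & !m[, "ctcf"])
  nC <- sum(!m[, "runx2"] & m[, "ctcf"])
  nTot <- length(dhs)
  nNeither <- nTot - nBoth - nR - nC
  inDhs <- function(tf) {
    if (!length(tf)) return(c(inside = 0, outside = 0))
    hit <- overlapsAny(granges(tf), granges(dhs), minoverlap = minOverlap,
                       ignore.strand = TRUE)
    c(inside = mean(hit), outside = mean(!hit))
  }
  r2 <- inDhs(runx2); ct <- inDhs(ctcf)
  new("RegulomeOverlapReport",
      stage = dhs@stage,
      counts = c(dhs_total = as.integer(nTot),
                 with_runx2_only = as.integer(nR),
                 with_ctcf_only = as.integer(nC),
                 with_both = as.integer(nBoth),
                 with_neither = as.integer(nNeither)),
      fractions = c(
        with_either = if (nTot > 0) (nR + nC + nBoth) / nTot else NA_real_,
        runx2_in_dhs = unname(r2["inside"]),
        ctcf_in_dhs = unname(ct["inside"]),
        runx2_outside_dhs = unname(r2["outside"]),
        ctcf_outside_dhs = unname(ct["outside"])))
}
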