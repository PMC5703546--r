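#' Read a chrom.sizes file
#'
#' Two-column tab-separated file: chromosome name, length in bp.
#'
#' @param path file path.
#' @return a [GenomeInfoDb::Seqinfo] carrying the chromosome lengths.
#' @export
readChromSizes <- function(path) {
  if (!file.exists(path)) stop("chrom.sizes file not found: ", path)
  tab <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = c("character", "integer"))
  if (anyDuplicated(tab[[1]])) stop("duplicate chromosome names in ", path)
  if (any(tab[[2]] <= 0L)) stop("chromosome lengths must be positive in ", path)
  Seqinfo(seqnames = tab[[1]], seqlengths = tab[[2]])
}

.splitBedLines <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  list(fields = strsplit(lines[keep], "\t", fixed = TRUE),
       lineno = which(keep))
}

#' Read a BED3+ file into a PeakSet
#'
#' Tab-separated, no header; `track`/`browser`/comment lines are skipped.
#' Columns beyond 6 are ignored; column 5 is kept as `score` when numeric.
#' BED coordinates (0-based half-open) are converted to the 1-based closed
#' GRanges convention internally.
#'
#' @param path file path.
#' @param chromsizes a `Seqinfo` governing the genome.
#' @param label label for the resulting set (default: file base name).
#' @return a sorted [PeakSet].
#' @examples
#' si <- GenomeInfoDb::Seqinfo("chr1", 1000)
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t0\t100", f)
#' readBed(f, si)
#' @export
readBed <- function(path, chromsizes, label = NULL) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (is.null(label)) label <- sub("\\.bed$", "", basename(path))
  parsed <- .splitBedLines(path)
  if (!length(parsed$fields))
    return(PeakSet(GRanges(seqinfo = chromsizes), label = label))
  nf <- lengths(parsed$fields)
  if (any(nf < 3L))
    stop("BED parse error at line ", parsed$lineno[which(nf < 3L)[1]],
         ": fewer than 3 tab-separated fields")
  chrom <- vapply(parsed$fields, `[[`, character(1), 1L)
  s0 <- suppressWarnings(as.numeric(vapply(parsed$fields, `[[`, character(1), 2L)))
  e0 <- suppressWarnings(as.numeric(vapply(parsed$fields, `[[`, character(1), 3L)))
  bad <- is.na(s0) | is.na(e0) | s0 != floor(s0) | e0 != floor(e0)
  if (any(bad))
    stop("BED parse error at line ", parsed$lineno[which(bad)[1]],
         ": non-integer coordinates")
  if (any(s0 < 0))
    stop("BED parse error at line ", parsed$lineno[which(s0 < 0)[1]],
         ": negative start")
  if (any(s0 >= e0))
    stop("BED parse error at line ", parsed$lineno[which(s0 >= e0)[1]],
         ": start >= end")
  unknown <- !(chrom %in% seqlevels(chromsizes))
  if (any(unknown))
    stop("BED parse error at line ", parsed$lineno[which(unknown)[1]],
         ": unknown chromosome '", chrom[which(unknown)[1]], "'")
  sl <- seqlengths(chromsizes)
  beyond <- e0 > sl[chrom]
  if (any(beyond))
    stop("BED parse error at line ", parsed$lineno[which(beyond)[1]],
         ": end beyond chromosome length")
  score <- rep(NA_real_, length(chrom))
  has5 <- nf >= 5L
  score[has5] <- suppressWarnings(as.numeric(
    vapply(parsed$fields[has5], `[[`, character(1), 5L)))
  gr <- GRanges(chrom, IRanges(start = s0 + 1, end = e0), seqinfo = chromsizes)
  if (any(!is.na(score))) gr$score <- score
  PeakSet(gr, label = label)
}

#' Write a PeakSet as BED6
#'
#' Emits `chrom  start  end  name  score  strand` with 0-based half-open
#' coordinates, `name = <label>_<index>`, score 0 where absent and strand
#' `'.'`. `readBed(writeBed(x))` reproduces coordinates and scores exactly.
#'
#' @param peaks a [PeakSet].
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
writeBed <- function(peaks, path) {
  stopifnot(is(peaks, "PeakSet") || is(peaks, "GRanges"))
  label <- if (is(peaks, "PeakSet") && !is.na(peaks@label)) peaks@label else "region"
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!length(peaks)) return(invisible(path))
  score <- if (!is.null(peaks$score)) peaks$score else rep(0, length(peaks))
  score[is.na(score)] <- 0
  lines <- paste(as.character(seqnames(peaks)), start(peaks) - 1L, end(peaks),
                 paste0(label, "_", seq_along(peaks)),
                 vapply(score, function(s) format(s, digits = 15, scientific = FALSE),
                        character(1)),
                 ".", sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

.parseIntList <- function(x) as.numeric(strsplit(sub(",$", "", x), ",", fixed = TRUE)[[1]])

#' Read gene models (BED12 or 7-column gene table)
#'
#' Accepts either BED12 or a minimal tab-separated gene table with columns
#' `gene_id, chrom, strand, txStart, txEnd, exonStarts, exonEnds`
#' (0-based half-open, exon lists comma-separated). Multi-transcript genes
#' are collapsed to one model per gene id using the longest transcript
#' (`collapse = "longest"`), or kept per-transcript (`collapse = "none"`,
#' transcript ids suffixed to make ids unique).
#'
#' @param path file path.
#' @param chromsizes a `Seqinfo`.
#' @param collapse `"longest"` (default) or `"none"`.
#' @return a [GeneAnnotation].
#' @export
readAnnotation <- function(path, chromsizes, collapse = c("longest", "none")) {
  collapse <- match.arg(collapse)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  parsed <- .splitBedLines(path)
  if (!length(parsed$fields)) {
    warning("empty annotation: no gene models")
    g <- GRanges(seqinfo = chromsizes)
    names(g) <- character(0)
    return(new("GeneAnnotation", genes = g, exons = GRangesList()))
  }
  nf <- lengths(parsed$fields)
  bed12 <- all(nf >= 12L)
  rec <- lapply(seq_along(parsed$fields), function(i) {
    f <- parsed$fields[[i]]
    ln <- parsed$lineno[i]
    if (bed12) {
      id <- f[[4]]; chrom <- f[[1]]; strand <- f[[6]]
      txs <- as.numeric(f[[2]]); txe <- as.numeric(f[[3]])
      sizes <- .parseIntList(f[[11]]); offs <- .parseIntList(f[[12]])
      es <- txs + offs; ee <- es + sizes
    } else {
      if (length(f) < 7L)
        stop("annotation parse error at line ", ln, ": expected 7 columns")
      id <- f[[1]]; chrom <- f[[2]]; strand <- f[[3]]
      txs <- as.numeric(f[[4]]); txe <- as.numeric(f[[5]])
      es <- .parseIntList(f[[6]]); ee <- .parseIntList(f[[7]])
    }
    if (is.na(txs) || is.na(txe) || txs >= txe)
      stop("annotation parse error at line ", ln, ": bad gene span")
    if (!strand %in% c("+", "-"))
      stop("annotation parse error at line ", ln, ": unknown strand '", strand, "'")
    if (!chrom %in% seqlevels(chromsizes))
      stop("annotation parse error at line ", ln, ": unknown chromosome '", chrom, "'")
    if (length(es) != length(ee) || !length(es) || any(es >= ee))
      stop("annotation parse error at line ", ln, ": malformed exon lists")
    if (any(es < txs) || any(ee > txe))
      stop("annotation parse error at line ", ln, ": exon outside gene span")
    list(id = id, chrom = chrom, strand = strand, txs = txs, txe = txe,
         es = sort(es), ee = sort(ee))
  })
  ids <- vapply(rec, `[[`, character(1), "id")
  if (collapse == "longest" && anyDuplicated(ids)) {
    len <- vapply(rec, function(r) r$txe - r$txs, numeric(1))
    keep <- unlist(lapply(split(seq_along(rec), ids),
                          function(ix) ix[which.max(len[ix])]))
    rec <- rec[sort(keep)]
    ids <- vapply(rec, `[[`, character(1), "id")
  } else if (anyDuplicated(ids)) {
    ids <- make.unique(ids, sep = "_tx")
  }
  genes <- GRanges(vapply(rec, `[[`, character(1), "chrom"),
                   IRanges(start = vapply(rec, `[[`, numeric(1), "txs") + 1,
                           end = vapply(rec, `[[`, numeric(1), "txe")),
                   strand = vapply(rec, `[[`, character(1), "strand"),
                   seqinfo = chromsizes)
  names(genes) <- ids
  exons <- GRangesList(lapply(seq_along(rec), function(i) {
    r <- rec[[i]]
    GRanges(r$chrom, IRanges(start = r$es + 1, end = r$ee),
            strand = r$strand, seqinfo = chromsizes)
  }))
  names(exons) <- ids
  new("GeneAnnotation", genes = genes, exons = exons)
}

#' Read a per-stage expression table
#'
#' Tab-separated with a header: `gene_id` followed by one column of
#' non-negative linear-scale expression values per stage.
#'
#' @param path file path.
#' @return data.frame with rownames = gene ids and one numeric column per
#'   stage.
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  tab <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs gene_id plus >=1 stage column")
  if (anyDuplicated(tab[[1]])) stop("duplicate gene ids in expression table")
  vals <- tab[, -1, drop = FALSE]
  if (any(vapply(vals, function(v) any(!is.finite(v) | v < 0), logical(1))))
    stop("expression values must be finite and >= 0")
  rownames(vals) <- tab[[1]]
  vals
}
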