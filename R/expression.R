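#' Fold-change expression classes between two stages
#'
#' With pseudocounted ratio `r = (b + pseudocount) / (a + pseudocount)`, a
#' gene is `UP` when `r >= foldThreshold`, `DOWN` when `r <= 1/foldThreshold`
#' and `UNCHANGED` otherwise. The boundary is inclusive: an exactly
#' two-fold change counts as changed. Swapping the stages maps UP to DOWN
#' and leaves UNCHANGED fixed.
#'
#' @param expr data.frame from [readExpression()] (rownames = gene ids, one
#'   numeric column per stage).
#' @param stageA,stageB column names of the baseline and comparison stages.
#' @param foldThreshold fold-change threshold (> 1; default 2).
#' @param pseudocount added to both values before the ratio (default 1).
#' @return data.frame with `gene_id`, `class` (factor UP/DOWN/UNCHANGED) and
#'   `log2_ratio`; threshold recorded in `attr(, "params")`.
#' @export
foldChangeClasses <- function(expr, stageA, stageB, foldThreshold = 2,
                              pseudocount = 1) {
  if (foldThreshold <= 1) stop("'foldThreshold' must be > 1")
  missing <- setdiff(c(stageA, stageB), colnames(expr))
  if (length(missing))
    stop("stage column(s) not in expression table: ",
         paste(missing, collapse = ", "))
  a <- expr[[stageA]]; b <- expr[[stageB]]
  r <- (b + pseudocount) / (a + pseudocount)
  cls <- ifelse(r >= foldThreshold, "UP",
                ifelse(r <= 1 / foldThreshold, "DOWN", "UNCHANGED"))
  out <- data.frame(gene_id = rownames(expr),
                    class = factor(cls, levels = c("UP", "DOWN", "UNCHANGED")),
                    log2_ratio = log2(r), stringsAsFactors = FALSE)
  attr(out, "params") <- list(stageA = stageA, stageB = stageB,
                              foldThreshold = foldThreshold,
                              pseudocount = pseudocount)
  out
}

#' Cross-tabulate expression classes against TES-flank groups
#'
#' Counts every (expression class x TES group) combination over the shared
#' gene universe (the intersection of the two id sets; its size is recorded).
#' Margins equal the input class/group counts restricted to the
#' intersection.
#'
#' @param classes data.frame from [foldChangeClasses()].
#' @param tesGroups data.frame from [classifyTesFlank()].
#' @return a `table` (classes x groups) with attribute `n_shared` giving the
#'   intersection size.
#' @export
crossTabulate <- function(classes, tesGroups) {
  shared <- intersect(classes$gene_id, tesGroups$gene_id)
  if (!length(shared)) stop("no shared genes between expression and TES groups")
  cl <- classes$class[match(shared, classes$gene_id)]
  gp <- tesGroups$group[match(shared, tesGroups$gene_id)]
  tab <- table(class = cl, group = gp)
  attr(tab, "n_shared") <- length(shared)
  tab
}
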