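.defaultParams <- function() {
  list(merge_gap = 0L, min_overlap_bp = 1L,
       promoter_up = 2000L, promoter_down = 500L,
       bin_bp = 25L, flank = 2000L, body_bins = 100L,
       tes_centers = c(500, 1000), tes_tolerance = 250,
       min_summit = NULL, min_summit_quantile = NULL, min_summit_ratio = 3,
       fold_threshold = 2, pseudocount = 1,
       profile_stage = NULL, expr_stages = NULL)
}

#' Validate a pipeline configuration
#'
#' Accepts a config as an R list or a path to a JSON file. All problems are
#' collected and reported together, not first-only. Required fields:
#' `chrom_sizes`, `stages`, and per-stage replicate peak paths under
#' `peaks`; `annotation`, `tf`, `signal` and `expression` are optional
#' (stages of the analysis relying on an absent input are skipped).
#'
#' @param config list or JSON file path.
#' @return the validated config (with `params` filled with defaults) or an
#'   error listing every problem.
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  errs <- character()
  need <- function(cond, msg) if (!cond) errs <<- c(errs, msg)
  need(!is.null(config$chrom_sizes), "missing 'chrom_sizes'")
  if (!is.null(config$chrom_sizes))
    need(file.exists(config$chrom_sizes),
         paste0("chrom_sizes file not found: ", config$chrom_sizes))
  need(length(config$stages) >= 2, "'stages' must list >= 2 stage names")
  for (st in config$stages) {
    ps <- config$peaks[[st]]
    need(length(ps) == 2,
         paste0("stage '", st, "' needs exactly 2 replicate peak paths"))
    for (f in ps)
      need(file.exists(f), paste0("peak file not found: ", f))
  }
  for (f in c("annotation", "expression"))
    if (!is.null(config[[f]]))
      need(file.exists(config[[f]]),
           paste0(f, " file not found: ", config[[f]]))
  for (st in names(config$tf %||% list()))
    for (f in unlist(config$tf[[st]]))
      need(file.exists(f), paste0("TF peak file not found: ", f))
  for (st in names(config$signal %||% list()))
    need(file.exists(config$signal[[st]]),
         paste0("signal file not found: ", config$signal[[st]]))
  params <- utils::modifyList(.defaultParams(), config$params %||% list())
  need(params[["merge_gap"]] >= 0, "'merge_gap' must be >= 0")
  need(params[["min_overlap_bp"]] >= 1, "'min_overlap_bp' must be >= 1")
  need(params[["promoter_up"]] >= 0 && params[["promoter_down"]] >= 0,
       "promoter window sizes must be >= 0")
  need(params[["flank"]] > 0, "'flank' must be > 0")
  need(params[["flank"]] %% params[["bin_bp"]] == 0,
       "'flank' must be a multiple of 'bin_bp'")
  need(params[["fold_threshold"]] > 1, "'fold_threshold' must be > 1")
  need(all(params[["tes_centers"]] > 0) && all(params[["tes_centers"]] <= params[["flank"]]),
       "'tes_centers' must be positive and within the flank")
  if (length(params[["tes_centers"]]) > 1)
    need(min(diff(sort(params[["tes_centers"]]))) >= 2 * params[["tes_tolerance"]],
         "'tes_tolerance' too large: classification windows overlap")
  if (length(errs))
    stop("invalid pipeline config:\n  - ", paste(errs, collapse = "\n  - "))
  config$params <- params
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis on an in-memory bundle
#'
#' Executes consensus -> Venn -> differential -> partition -> TF overlap ->
#' signal profiles -> expression -> cross-tabulation on objects of the shape
#' produced by [generateSynthetic()]. Conservation identities (Venn pattern
#' sums, lost + shared = stage size, crosstab margins) are re-checked before
#' the report is returned and any violation raises an error naming the
#' stage.
#'
#' @param bundle list with `chromSizes`, `peaks` (stage -> rep1/rep2
#'   [PeakSet]s) and optionally `genes`, `tf`, `tracks`, `expression`.
#' @param params parameter list as in [validateConfig()]; defaults applied.
#' @param outdir optional directory for artifact files (TSV/BED/JSON).
#' @return a summary report list (also serialized to `summary.json` under
#'   `outdir` when given).
#' @export
runBundle <- function(bundle, params = list(), outdir = NULL) {
  params <- utils::modifyList(.defaultParams(), params)
  stages <- bundle$stages %||% names(bundle$peaks)
  report <- list(stages = stages)

  ## consensus ---------------------------------------------------------
  consensus <- lapply(stages, function(st)
    replicateConsensus(bundle$peaks[[st]][[1]], bundle$peaks[[st]][[2]],
                       stage = st))
  names(consensus) <- stages
  report$consensus_counts <- setNames(
    vapply(consensus, length, integer(1)), stages)

  ## Venn --------------------------------------------------------------
  venn <- stageVenn(consensus)
  if (sum(vennCounts(venn)) != length(vennUniverse(venn)))
    stop("pipeline invariant violated at stage 'venn': pattern counts do not sum to universe")
  report$unique_sites <- length(vennUniverse(venn))
  report$venn_counts <- vennCounts(venn)
  allPat <- paste(stages, collapse = "&")
  exclusive <- sum(vennCounts(venn)[stages], na.rm = TRUE)
  report$common_all_stages <- unname(vennCounts(venn)[allPat])
  report$stage_exclusive_total <- exclusive
  report$dynamic_fraction <- if (report$unique_sites > 0)
    1 - (report$common_all_stages %||% 0) / report$unique_sites else NA_real_

  ## pairwise dynamics --------------------------------------------------
  pairs <- if (length(stages) >= 2)
    lapply(seq_len(length(stages) - 1L), function(i) c(stages[i], stages[i + 1L]))
  else list()
  report$comparisons <- lapply(pairs, function(pr) {
    cmp <- differentialSites(consensus[[pr[1]]], consensus[[pr[2]]])
    cc <- comparisonCounts(cmp)
    if (cc["n_lost"] + cc["n_shared_from"] != length(consensus[[pr[1]]]) ||
        cc["n_gained"] + cc["n_shared_to"] != length(consensus[[pr[2]]]))
      stop("pipeline invariant violated at stage 'differential (",
           pr[1], "->", pr[2], ")': conservation identity failed")
    list(from = pr[1], to = pr[2], n_lost = unname(cc["n_lost"]),
         n_gained = unname(cc["n_gained"]),
         n_shared_from = unname(cc["n_shared_from"]),
         n_shared_to = unname(cc["n_shared_to"]),
         loss_gain_ratio = lossGainRatio(cmp), comparison = cmp)
  })
  names(report$comparisons) <- vapply(pairs, paste, character(1), collapse = "_to_")

  ## partitions ----------------------------------------------------------
  if (!is.null(bundle$genes) && length(bundle$genes)) {
    parts <- buildPartitions(bundle$genes, bundle$chromSizes,
                             promoterUp = params[["promoter_up"]],
                             promoterDown = params[["promoter_down"]])
    report$partitions <- lapply(consensus, function(cs) {
      cl <- classifyPeaks(cs, parts)
      if (length(cs) && sum(cl$counts) < cl$total)
        stop("pipeline invariant violated at stage 'partition': uncategorized peaks")
      cl[c("counts", "fractions", "total")]
    })
    report$.parts <- parts
  } else report$partitions <- "skipped"

  ## TF overlap ----------------------------------------------------------
  if (!is.null(bundle$tf) && length(bundle$tf)) {
    report$regulome <- lapply(stages, function(st) {
      tfs <- bundle$tf[[st]]
      if (is.null(tfs)) return("skipped")
      ro <- regulomeOverlap(consensus[[st]], tfs$runx2, tfs$ctcf,
                            minOverlap = params[["min_overlap_bp"]])
      list(counts = overlapCounts(ro), fractions = overlapFractions(ro))
    })
    names(report$regulome) <- stages
  } else report$regulome <- "skipped"

  ## signal profiles ------------------------------------------------------
  profStage <- params[["profile_stage"]] %||% stages[min(2L, length(stages))]
  if (!is.null(bundle$tracks) && !is.null(bundle$tracks[[profStage]]) &&
      !is.null(bundle$genes) && length(bundle$genes)) {
    masked <- maskToPeaks(bundle$tracks[[profStage]], consensus[[profStage]])
    prof <- suppressWarnings(
      tesProfile(masked, bundle$genes, flank = params[["flank"]]))
    tesGroups <- classifyTesFlank(prof, centers = params[["tes_centers"]],
                                  tolerance = params[["tes_tolerance"]],
                                  minSummit = params[["min_summit"]],
                                  minSummitQuantile = params[["min_summit_quantile"]],
                                  minSummitRatio = params[["min_summit_ratio"]])
    report$tes_profile_stage <- profStage
    report$tes_group_sizes <- table(tesGroups$group)
    report$.tes_profile <- prof
    report$.tes_groups <- tesGroups
    grpIds <- split(tesGroups$gene_id, tesGroups$group)
    report$.aggregate_curves <- lapply(
      grpIds[vapply(grpIds, length, integer(1)) > 0],
      function(ids) aggregateGroup(prof, ids))
  } else report$tes_group_sizes <- "skipped"

  ## expression -----------------------------------------------------------
  exprStages <- params[["expr_stages"]] %||% stages[seq_len(min(2L, length(stages)))]
  if (!is.null(bundle$expression)) {
    classes <- foldChangeClasses(bundle$expression, exprStages[1],
                                 exprStages[2],
                                 foldThreshold = params[["fold_threshold"]],
                                 pseudocount = params[["pseudocount"]])
    report$expression_class_sizes <- table(classes$class)
    report$.expression_classes <- classes
    if (!is.null(report$.tes_groups)) {
      tab <- crossTabulate(classes, report$.tes_groups)
      sharedIds <- intersect(classes$gene_id, report$.tes_groups$gene_id)
      clShared <- table(classes$class[match(sharedIds, classes$gene_id)])
      if (!identical(as.integer(rowSums(tab)),
                     as.integer(clShared[rownames(tab)])))
        stop("pipeline invariant violated at stage 'crosstab': margins do not match class sizes")
      report$crosstab <- tab
    }
  } else report$expression_class_sizes <- "skipped"

  if (!is.null(outdir)) .writeReportArtifacts(report, outdir)
  report
}

#' Run the pipeline from a file-based configuration
#'
#' Reads every referenced file (chrom sizes, per-stage replicate BEDs, gene
#' annotation, TF BEDs, bedGraph signal, expression TSV), then delegates to
#' [runBundle()]. Optional inputs that are absent simply mark their analysis
#' section `"skipped"`.
#'
#' @param config list or JSON path accepted by [validateConfig()].
#' @param outdir output directory for artifacts (overrides `config$outdir`).
#' @return the summary report list.
#' @export
runPipeline <- function(config, outdir = NULL) {
  config <- validateConfig(config)
  si <- readChromSizes(config$chrom_sizes)
  stages <- config$stages
  bundle <- list(chromSizes = si, stages = stages)
  bundle$peaks <- lapply(setNames(stages, stages), function(st)
    list(rep1 = readBed(config$peaks[[st]][1], si),
         rep2 = readBed(config$peaks[[st]][2], si)))
  if (!is.null(config$annotation))
    bundle$genes <- readAnnotation(config$annotation, si)
  if (!is.null(config$tf))
    bundle$tf <- lapply(config$tf, function(x)
      list(runx2 = readBed(x$runx2, si), ctcf = readBed(x$ctcf, si)))
  if (!is.null(config$signal))
    bundle$tracks <- lapply(config$signal, function(f)
      readBedGraph(f, si, binWidth = config$params[["bin_bp"]]))
  if (!is.null(config$expression))
    bundle$expression <- readExpression(config$expression)
  outdir <- outdir %||% config$outdir
  report <- runBundle(bundle, config$params, outdir = outdir)
  report$provenance <- .provenance(config)
  if (!is.null(outdir)) .writeSummaryJson(report, outdir)
  report
}

.provenance <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, force = TRUE)
  list(config_md5 = unname(tools::md5sum(tmp)),
       package = "dhsdyn",
       version = as.character(utils::packageVersion("dhsdyn")),
       timestamp_free = TRUE)
}

.reportJsonable <- function(report) {
  keep <- report[!startsWith(names(report), ".")]
  rapply(keep, f = function(x) {
    if (is.table(x)) as.list(setNames(as.integer(x), names(x)))
    else if (!is.null(names(x)) && is.atomic(x)) as.list(x)
    else x
  }, classes = c("table", "integer", "numeric", "character"),
  how = "replace")
}

.writeSummaryJson <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  keep <- report[!startsWith(names(report), ".")]
  keep$comparisons <- lapply(keep$comparisons, function(x)
    x[setdiff(names(x), "comparison")])
  keep <- rapply(keep, function(x) {
    if (is.table(x)) as.list(setNames(as.vector(x), names(x))) else x
  }, classes = "table", how = "replace")
  jsonlite::write_json(keep, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  invisible(file.path(outdir, "summary.json"))
}

.writeReportArtifacts <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) write.table(df, file.path(outdir, name),
                                       sep = "\t", quote = FALSE,
                                       row.names = FALSE)
  if (!is.null(report$venn_counts))
    wt(data.frame(pattern = names(report$venn_counts),
                  count = as.integer(report$venn_counts)), "venn_counts.tsv")
  if (length(report$comparisons)) {
    wt(do.call(rbind, lapply(report$comparisons, function(x)
      data.frame(from = x$from, to = x$to, n_lost = x$n_lost,
                 n_gained = x$n_gained, n_shared_from = x$n_shared_from,
                 n_shared_to = x$n_shared_to,
                 loss_gain_ratio = x$loss_gain_ratio))),
      "stage_comparison.tsv")
    for (x in report$comparisons) {
      writeBed(x$comparison@lost,
               file.path(outdir, paste0("lost_", x$from, "_to_", x$to, ".bed")))
      writeBed(x$comparison@gained,
               file.path(outdir, paste0("gained_", x$from, "_to_", x$to, ".bed")))
    }
  }
  if (is.list(report$partitions))
    wt(do.call(rbind, lapply(names(report$partitions), function(st) {
      p <- report$partitions[[st]]
      data.frame(stage = st, category = names(p$counts),
                 count = as.integer(p$counts),
                 fraction = as.numeric(p$fractions))
    })), "partition_counts.tsv")
  if (is.list(report$regulome))
    wt(do.call(rbind, lapply(names(report$regulome), function(st) {
      r <- report$regulome[[st]]
      if (!is.list(r)) return(NULL)
      data.frame(stage = st,
                 metric = c(names(r$counts), names(r$fractions)),
                 value = c(as.numeric(r$counts), as.numeric(r$fractions)))
    })), "regulome_overlap.tsv")
  if (!is.null(report$.tes_profile)) {
    prof <- profileMatrix(report$.tes_profile)
    wt(data.frame(gene_id = rownames(prof), prof, check.names = FALSE),
       "tes_profile.tsv")
    wt(report$.tes_groups, "tes_groups.tsv")
    if (!is.null(report$.aggregate_curves))
      wt(do.call(rbind, lapply(names(report$.aggregate_curves), function(gp) {
        ag <- report$.aggregate_curves[[gp]]
        data.frame(group = gp, offset = ag$offsets, mean = ag$mean,
                   se = ag$se, n = ag$n)
      })), "aggregate_curves.tsv")
  }
  if (!is.null(report$.expression_classes))
    wt(report$.expression_classes, "expression_classes.tsv")
  if (!is.null(report$crosstab))
    wt(as.data.frame(report$crosstab), "tes_expression_crosstab.tsv")
  invisible(outdir)
}

#' Compare pipeline results with a synthetic truth table
#'
#' Quantifies, per planted quantity, whether the pipeline recovered the
#' generator's ground truth: exact equality for consensus counts and Venn
#' pattern counts, exact class counts for TF co-occupancy, and per-gene
#' recovery rates for TES-flank groups and expression classes.
#'
#' @param report result of [runBundle()] / [runPipeline()] on the generated
#'   bundle.
#' @param truth the `truth` component of [generateSynthetic()].
#' @return list with logical `*_exact` flags and numeric recovery rates in
#'   \[0, 1\].
#' @export
verifyTruth <- function(report, truth) {
  if (is.null(report$consensus_counts)) stop("report is missing pipeline outputs")
  out <- list()
  out$consensus_exact <- identical(
    as.integer(report$consensus_counts[names(truth$consensus_counts)]),
    as.integer(truth$consensus_counts))
  tp <- truth$pattern_counts
  rp <- report$venn_counts
  allPat <- union(names(tp), names(rp))
  out$venn_exact <- isTRUE(all(
    vapply(allPat, function(p) {
      a <- if (p %in% names(tp)) tp[[p]] else 0L
      b <- if (p %in% names(rp)) rp[[p]] else 0L
      a == b
    }, logical(1))))
  out$unique_sites_exact <- report$unique_sites == truth$unique_sites
  if (is.list(report$regulome)) {
    out$tf_exact <- all(vapply(names(truth$tf), function(st) {
      r <- report$regulome[[st]]
      if (!is.list(r)) return(FALSE)
      tt <- truth$tf[[st]]$counts
      r$counts[["with_runx2_only"]] == tt$runx2_only &&
        r$counts[["with_ctcf_only"]] == tt$ctcf_only &&
        r$counts[["with_both"]] == tt$both &&
        r$counts[["with_neither"]] == tt$neither
    }, logical(1)))
  }
  if (!is.null(report$.tes_groups)) {
    tg <- report$.tes_groups
    planted <- truth$tes_groups[tg$gene_id]
    out$tes_recovery <- mean(as.character(tg$group) == planted)
  }
  if (!is.null(report$.expression_classes)) {
    ec <- report$.expression_classes
    planted <- truth$expression_classes[ec$gene_id]
    out$expression_recovery <- mean(as.character(ec$class) == planted)
  }
  if (!is.null(report$crosstab) && !is.null(out$tes_recovery)) {
    tg <- report$.tes_groups
    grpOf <- c(UP = "TES_PLUS_1000", DOWN = "TES_PLUS_500", UNCHANGED = "NONE")
    shared <- intersect(report$.expression_classes$gene_id, tg$gene_id)
    cl <- as.character(report$.expression_classes$class[
      match(shared, report$.expression_classes$gene_id)])
    gp <- as.character(tg$group[match(shared, tg$gene_id)])
    out$crosstab_diagonal_concordance <- mean(grpOf[cl] == gp)
  }
  out
}
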