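#' Full statistical report on a cohort of methylation estimates
#'
#' Computes, from a cohort table (one row per subject with `group`,
#' clinical-category columns, and per-gene `level_*`/`state_*` columns):
#' per-group per-gene mean levels and methylation-state frequencies; the
#' fraction of subjects with at least one methylated gene; per-gene ROC of
#' levels against group with the Youden-optimal operating point; CART trees
#' on levels and on states with their apparent (training-set) confusion
#' metrics; and Fisher's exact tests of each gene against each clinical
#' category among the cancer subjects - one test on states and one on
#' tertile-binned levels, since a continuous level cannot enter a
#' contingency table directly.
#'
#' @param records cohort data.frame (see [simulateCohort()]).
#' @param genes gene names; default: inferred from `level_*` columns.
#' @param threshold state threshold used for the any-gene summary.
#' @param minLeaf,maxDepth CART stopping parameters.
#' @return list of data.frames/objects: groupSummary, anyGene, roc,
#'   cartLevels, cartStates (each with tree, predictions, metrics), fisher.
#' @examples
#' rep <- cohortReport(simulateCohort(cohortConfig(seed = 3)))
#' rep$anyGene
#' @export
cohortReport <- function(records, genes = NULL, threshold = 0.05,
                         minLeaf = 5L, maxDepth = 3L) {
  if (!nrow(records)) stopArgument("empty cohort")
  if (!"group" %in% names(records))
    stopConfig("cohort table lacks required column 'group'")
  if (is.null(genes))
    genes <- sub("^level_", "", grep("^level_", names(records), value = TRUE))
  if (!length(genes)) stopConfig("cohort table has no level_<gene> columns")
  lvlCols <- paste0("level_", genes)
  stCols <- paste0("state_", genes)
  missing <- setdiff(c(lvlCols, stCols), names(records))
  if (length(missing))
    stopConfig(sprintf("cohort table lacks column(s): %s",
                       paste(missing, collapse = ", ")))

  groups <- c("cancer", "control")
  groupSummary <- do.call(rbind, lapply(groups, function(grp) {
    d <- records[records$group == grp, , drop = FALSE]
    do.call(rbind, lapply(genes, function(g) data.frame(
      group = grp, gene = g, n = nrow(d),
      mean_level = mean(d[[paste0("level_", g)]]),
      methylated_frequency = mean(d[[paste0("state_", g)]] == "methylated"),
      stringsAsFactors = FALSE)))
  }))

  anyMeth <- apply(records[, lvlCols, drop = FALSE] >= threshold, 1, any)
  anyGene <- do.call(rbind, lapply(groups, function(grp) {
    sel <- records$group == grp
    data.frame(group = grp, n = sum(sel),
               any_gene_methylated = mean(anyMeth[sel]),
               stringsAsFactors = FALSE)
  }))

  roc <- do.call(rbind, lapply(genes, function(g) {
    r <- rocYouden(records[[paste0("level_", g)]], records$group,
                   positive = "cancer")
    data.frame(gene = g, auc = r$auc, threshold = r$threshold,
               sensitivity = r$sensitivity, specificity = r$specificity,
               accuracy = r$accuracy, stringsAsFactors = FALSE)
  }))

  fitEval <- function(features) {
    tree <- cartFit(features, records$group, minLeaf = minLeaf,
                    maxDepth = maxDepth)
    pred <- cartPredict(tree, features)
    list(tree = tree, predictions = pred,
         metrics = confusionMetrics(pred, records$group, positive = "cancer"))
  }
  featL <- records[, lvlCols, drop = FALSE]
  featS <- as.data.frame(lapply(records[, stCols, drop = FALSE],
                                function(x) as.numeric(x == "methylated")))
  names(featS) <- stCols
  cartLevels <- fitEval(featL)
  cartStates <- fitEval(featS)

  clinical <- intersect(c("gender", "age_band", "pack_years_band",
                          "stage_band", "histology"), names(records))
  cancer <- records[records$group == "cancer", , drop = FALSE]
  fisher <- do.call(rbind, lapply(clinical, function(feat) {
    do.call(rbind, lapply(genes, function(g) {
      cat0 <- cancer[[feat]]
      keep <- !is.na(cat0)
      lvl <- cancer[[paste0("level_", g)]][keep]
      st <- cancer[[paste0("state_", g)]][keep]
      cat <- cat0[keep]
      data.frame(
        clinical_feature = feat, gene = g,
        p_level_tertiles = safeFisher(tertileBin(lvl), cat),
        p_state = safeFisher(st, cat),
        stringsAsFactors = FALSE)
    }))
  }))

  list(groupSummary = groupSummary, anyGene = anyGene, roc = roc,
       cartLevels = cartLevels, cartStates = cartStates, fisher = fisher)
}

# Tertile bins of a continuous level; collapses to fewer bins when the
# empirical tertiles tie (e.g. many exact zeros).
tertileBin <- function(x) {
  br <- unique(stats::quantile(x, c(0, 1/3, 2/3, 1)))
  if (length(br) < 3L) {
    # degenerate spread: split at the median of distinct values instead
    u <- sort(unique(x))
    if (length(u) < 2L) return(rep("T1", length(x)))
    br <- c(min(x), u[ceiling(length(u) / 2)], max(x))
    br <- unique(br)
  }
  as.character(cut(x, breaks = br, include.lowest = TRUE,
                   labels = paste0("T", seq_len(length(br) - 1L))))
}

# Fisher p with empty categories dropped; NA when the table degenerates or
# exceeds the enumeration budget.
safeFisher <- function(a, b) {
  tab <- table(a, b)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  tryCatch(fisherExact(tab),
           msersCapacityError = function(e) NA_real_)
}

#' Write a cohort report to delimited files
#'
#' Writes groupSummary.csv, anyGene.csv, roc.csv, fisher.csv, the two trees
#' as indented text and JSON, and cartMetrics.csv into `dir`.
#'
#' @param report output of [cohortReport()].
#' @param dir destination directory (created if needed).
#' @return Invisibly, the directory.
#' @export
writeCohortReport <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    utils::write.csv(df, file.path(dir, name), row.names = FALSE, quote = FALSE)
  wr(report$groupSummary, "groupSummary.csv")
  wr(report$anyGene, "anyGene.csv")
  wr(report$roc, "roc.csv")
  wr(report$fisher, "fisher.csv")
  metrics <- do.call(rbind, lapply(c("cartLevels", "cartStates"), function(k) {
    m <- report[[k]]$metrics
    data.frame(model = k, sensitivity = m$sensitivity,
               specificity = m$specificity, accuracy = m$accuracy)
  }))
  wr(metrics, "cartMetrics.csv")
  for (k in c("cartLevels", "cartStates")) {
    writeLines(formatTree(report[[k]]$tree), file.path(dir, paste0(k, ".txt")))
    jsonlite::write_json(treeToList(report[[k]]$tree),
                         file.path(dir, paste0(k, ".json")),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
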