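# Verification and cohort statistics: Bland-Altman agreement, ROC with
# Youden-optimal cutoff, CART, Fisher's exact test, confusion metrics.

#' Bland-Altman agreement statistics
#'
#' Differences are estimate minus truth; limits of agreement are
#' `mean_diff +/- 1.96 * sd_diff`. The plotting coordinates (mean of the
#' pair, difference) are returned alongside.
#'
#' @param estimates,truths equal-length numeric vectors of paired
#'   measurements.
#' @return list with elements pairs (data.frame estimate/truth/mean/diff),
#'   mean_diff, sd_diff, limits (length 2), max_abs_diff.
#' @examples
#' blandAltman(c(0.10, 0.50, 0.80), c(0.12, 0.47, 0.80))$max_abs_diff
#' @export
blandAltman <- function(estimates, truths) {
  if (length(estimates) != length(truths) || length(estimates) == 0L)
    stopArgument("estimates and truths must have equal nonzero length")
  d <- estimates - truths
  meanDiff <- mean(d)
  sdDiff <- stats::sd(d)
  list(pairs = data.frame(estimate = estimates, truth = truths,
                          mean = (estimates + truths) / 2, diff = d),
       mean_diff = meanDiff, sd_diff = sdDiff,
       limits = meanDiff + c(-1.96, 1.96) * sdDiff,
       max_abs_diff = max(abs(d)))
}

#' ROC analysis with Youden-optimal cutoff
#'
#' Thresholds are the midpoints between consecutive distinct scores plus
#' -Inf/+Inf sentinels; a sample is called positive when its score is at
#' least the threshold. The operating point maximizes Youden's
#' J = sensitivity + specificity - 1; ties are broken toward the lower
#' threshold (higher sensitivity). AUC by the trapezoidal rule.
#'
#' @param scores numeric per-sample scores (higher = more positive-like).
#' @param labels binary truth: logical, 0/1 numeric, or character/factor
#'   with `positive` naming the positive class.
#' @param positive label of the positive class for character/factor labels.
#' @return list with curve (data.frame threshold/sensitivity/specificity/
#'   youden), auc, threshold, sensitivity, specificity, accuracy (at the
#'   optimum).
#' @export
rocYouden <- function(scores, labels, positive = "cancer") {
  truth <- binarize(labels, positive)
  if (length(scores) != length(truth))
    stopArgument("scores and labels must have equal length")
  nPos <- sum(truth); nNeg <- sum(!truth)
  if (nPos == 0L || nNeg == 0L)
    stopArgument("degenerate labels: both classes must be present")
  s <- sort(unique(scores))
  thresholds <- c(-Inf, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2, Inf)
  sens <- spec <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    call <- scores >= thresholds[i]
    sens[i] <- sum(call & truth) / nPos
    spec[i] <- sum(!call & !truth) / nNeg
  }
  J <- sens + spec - 1
  best <- which(J == max(J))[1]  # thresholds ascend, first max = lowest cutoff
  # trapezoidal AUC over the ROC curve (FPR ascending)
  fpr <- 1 - spec; tpr <- sens
  ord <- order(fpr, tpr)
  auc <- sum(diff(fpr[ord]) * (tpr[ord][-1] + tpr[ord][-length(ord)]) / 2)
  acc <- (sens[best] * nPos + spec[best] * nNeg) / (nPos + nNeg)
  list(curve = data.frame(threshold = thresholds, sensitivity = sens,
                          specificity = spec, youden = J),
       auc = auc, threshold = thresholds[best], sensitivity = sens[best],
       specificity = spec[best], accuracy = acc)
}

binarize <- function(labels, positive) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      stopArgument("numeric labels must be 0/1")
    return(labels == 1)
  }
  as.character(labels) == positive
}

#' Confusion metrics of binary predictions
#'
#' @param predicted,actual binary label vectors (logical, 0/1, or
#'   character/factor with `positive`).
#' @param positive positive-class label for character/factor input.
#' @return list: sensitivity, specificity, accuracy (fractions).
#' @export
confusionMetrics <- function(predicted, actual, positive = "cancer") {
  pred <- binarize(predicted, positive)
  act <- binarize(actual, positive)
  if (length(pred) != length(act))
    stopArgument("predicted and actual must have equal length")
  if (!any(act) || all(act))
    stopArgument("degenerate labels: both classes must be present in actual")
  list(sensitivity = sum(pred & act) / sum(act),
       specificity = sum(!pred & !act) / sum(!act),
       accuracy = mean(pred == act))
}

#' Fisher's exact test on an r x c contingency table
#'
#' Exact p-value under the fixed-margins hypergeometric null: the summed
#' probability of all tables no more probable than the observed one (the
#' standard two-sided rule; 2 x 2 tables are a special case of the same
#' rule). Enumeration is refused for tables too large for exact computation.
#'
#' @param table matrix of non-negative integer counts, both margins nonzero.
#' @param maxTotal enumeration budget on the grand total.
#' @return The exact p-value.
#' @examples
#' fisherExact(matrix(c(3, 1, 1, 3), 2))  # 34/70
#' @export
fisherExact <- function(table, maxTotal = 200L) {
  tab <- as.matrix(table)
  if (any(is.na(tab)) || any(tab < 0) || any(tab != round(tab)))
    stopArgument("contingency table must contain non-negative integers")
  if (nrow(tab) < 2L || ncol(tab) < 2L)
    stopArgument("contingency table must be at least 2 x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopArgument("zero margin: every row and column must have a positive total")
  if (sum(tab) > maxTotal || nrow(tab) > 12L || ncol(tab) > 12L)
    stopCapacity(sprintf(
      "table too large for exact enumeration (total %d > %d or > 12 categories); bin categories first",
      sum(tab), maxTotal))
  stats::fisher.test(tab, workspace = 2e7)$p.value
}

## ---- CART ------------------------------------------------------------

giniImpurity <- function(labels, classes) {
  p <- tabulate(match(labels, classes), nbins = length(classes)) / length(labels)
  1 - sum(p^2)
}

bestSplit <- function(features, labels, classes, minLeaf) {
  n <- length(labels)
  best <- NULL
  for (j in seq_along(features)) {
    x <- features[[j]]
    vals <- sort(unique(x))
    if (length(vals) < 2L) next
    cuts <- (vals[-1] + vals[-length(vals)]) / 2
    for (t in cuts) {
      left <- x <= t
      nl <- sum(left)
      if (nl < minLeaf || n - nl < minLeaf) next
      g <- (nl * giniImpurity(labels[left], classes) +
            (n - nl) * giniImpurity(labels[!left], classes)) / n
      if (is.null(best) || g < best$gini - 1e-12) {
        best <- list(feature = names(features)[j], threshold = t, gini = g)
      }
    }
  }
  best
}

majorityClass <- function(labels, classPriority) {
  counts <- vapply(classPriority, function(cl) sum(labels == cl), integer(1))
  classPriority[which.max(counts)]  # priority order breaks ties
}

growTree <- function(features, labels, classes, classPriority, minLeaf,
                     maxDepth, depth) {
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  names(counts) <- classes
  leaf <- function() list(leaf = TRUE, class = majorityClass(labels, classPriority),
                          counts = counts, depth = depth)
  if (length(unique(labels)) == 1L || depth >= maxDepth ||
      length(labels) < 2L * minLeaf)
    return(leaf())
  split <- bestSplit(features, labels, classes, minLeaf)
  if (is.null(split)) return(leaf())
  sel <- features[[split$feature]] <= split$threshold
  list(leaf = FALSE, feature = split$feature, threshold = split$threshold,
       counts = counts, depth = depth,
       left = growTree(lapply(features, `[`, sel), labels[sel], classes,
                       classPriority, minLeaf, maxDepth, depth + 1L),
       right = growTree(lapply(features, `[`, !sel), labels[!sel], classes,
                        classPriority, minLeaf, maxDepth, depth + 1L))
}

#' Fit a CART classification tree
#'
#' Greedy recursive binary partitioning minimizing weighted Gini impurity.
#' Candidate thresholds are midpoints between consecutive distinct feature
#' values (binary 0/1 features split at 0.5); splitting stops when a node is
#' pure, the depth limit is reached, or a child would fall below `minLeaf`
#' samples. Leaves predict the majority class; ties go to the class most
#' frequent overall, then the lexicographically first. Split-score ties keep
#' the earliest feature (column order), then the lowest threshold.
#'
#' @param features data.frame of numeric (or 0/1) predictors.
#' @param labels class labels (character/factor/logical), two or more
#'   classes.
#' @param minLeaf minimum samples per leaf.
#' @param maxDepth maximum tree depth (root = 0).
#' @return Nested-list tree usable with [cartPredict()] and [formatTree()].
#' @examples
#' X <- data.frame(x = c(0.1, 0.2, 0.8, 0.9))
#' tr <- cartFit(X, c("a", "a", "b", "b"), minLeaf = 1)
#' cartPredict(tr, X)
#' @export
cartFit <- function(features, labels, minLeaf = 5L, maxDepth = 3L) {
  features <- as.data.frame(features)
  if (ncol(features) == 0L) stopArgument("empty feature set")
  features[] <- lapply(features, function(x) {
    if (is.logical(x)) return(as.numeric(x))
    if (is.character(x) || is.factor(x)) {
      u <- sort(unique(as.character(x)))
      if (length(u) > 2L)
        stopArgument("categorical features must be binary; recode first")
      return(as.numeric(as.character(x) == u[length(u)]))
    }
    as.numeric(x)
  })
  if (any(!vapply(features, function(x) all(is.finite(x)), logical(1))))
    stopArgument("features must be finite")
  labels <- as.character(labels)
  if (nrow(features) != length(labels))
    stopArgument("features and labels must have equal length")
  classes <- sort(unique(labels))
  overall <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  classPriority <- classes[order(-overall, classes)]
  tree <- growTree(features, labels, classes, classPriority,
                   as.integer(minLeaf), as.integer(maxDepth), 0L)
  attr(tree, "classes") <- classes
  class(tree) <- c("cartTree", "list")
  tree
}

#' Predict classes from a fitted CART tree
#'
#' @param tree a tree from [cartFit()].
#' @param features data.frame with the columns the tree splits on.
#' @return character vector of predicted classes.
#' @export
cartPredict <- function(tree, features) {
  features <- as.data.frame(features)
  features[] <- lapply(features, function(x) {
    if (is.logical(x)) return(as.numeric(x))
    if (is.character(x) || is.factor(x)) {
      u <- sort(unique(as.character(x)))
      return(as.numeric(as.character(x) == u[length(u)]))
    }
    as.numeric(x)
  })
  predictOne <- function(node, row) {
    while (!node$leaf) {
      node <- if (row[[node$feature]] <= node$threshold) node$left else node$right
    }
    node$class
  }
  vapply(seq_len(nrow(features)), function(i) predictOne(tree, features[i, , drop = FALSE]),
         character(1))
}

#' Serialize a CART tree
#'
#' @param tree a tree from [cartFit()].
#' @return `formatTree`: character vector of indented lines;
#'   `treeToList`: plain nested list (JSON-serializable).
#' @export
formatTree <- function(tree) {
  fmt <- function(node, indent) {
    pad <- strrep("  ", indent)
    cnt <- paste(sprintf("%s=%d", names(node$counts), node$counts), collapse = ", ")
    if (node$leaf)
      return(sprintf("%spredict %s  [%s]", pad, node$class, cnt))
    c(sprintf("%sif %s <= %.6g  [%s]", pad, node$feature, node$threshold, cnt),
      fmt(node$left, indent + 1L),
      sprintf("%selse (%s > %.6g)", pad, node$feature, node$threshold),
      fmt(node$right, indent + 1L))
  }
  fmt(tree, 0L)
}

#' @rdname formatTree
#' @export
treeToList <- function(tree) {
  strip <- function(node) {
    if (node$leaf)
      return(list(leaf = TRUE, class = node$class,
                  counts = as.list(node$counts), depth = node$depth))
    list(leaf = FALSE, feature = node$feature, threshold = node$threshold,
         counts = as.list(node$counts), depth = node$depth,
         left = strip(node$left), right = strip(node$right))
  }
  strip(tree)
}
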