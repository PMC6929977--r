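# Brute-force two-sided Fisher p for a 2x2 table: enumerate every table with
# the observed margins, sum the probabilities of those no more probable than
# the observed one.
bruteFisher2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- vapply(support, function(a) {
    b <- r1 - a; c <- c1 - a; d <- n - a - b - c
    exp(lchoose(r1, a) + lchoose(n - r1, c) - lchoose(n, c1))
  }, numeric(1))
  pObs <- probs[support == tab[1, 1]]
  sum(probs[probs <= pObs * (1 + 1e-7)])
}

test_that("Bland-Altman statistics match hand arithmetic", {
  ba <- blandAltman(c(0.10, 0.50, 0.80), c(0.12, 0.47, 0.80))
  expect_equal(ba$mean_diff, (-0.02 + 0.03 + 0.00) / 3)
  expect_equal(ba$max_abs_diff, 0.03)
  expect_equal(ba$pairs$mean, c(0.11, 0.485, 0.80))
  same <- blandAltman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$max_abs_diff, 0)
  expect_gte(same$max_abs_diff, abs(same$mean_diff))
  expect_error(blandAltman(1:3, 1:4), class = "msersArgumentError")
})

test_that("Bland-Altman limits contain ~95% of Gaussian differences", {
  set.seed(404)
  truth <- runif(1e4)
  est <- truth + rnorm(1e4, 0, 0.03)
  ba <- blandAltman(est, truth)
  frac <- mean(ba$pairs$diff >= ba$limits[1] & ba$pairs$diff <= ba$limits[2])
  expect_gt(frac, 0.95 - 3 * sqrt(0.05 * 0.95 / 1e4))
})

test_that("ROC finds the perfect separator", {
  r <- rocYouden(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = "1")
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$auc, 1)
  expect_gt(r$threshold, 2); expect_lt(r$threshold, 3)
})

test_that("ROC breaks Youden ties toward higher sensitivity", {
  r <- rocYouden(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_equal(max(r$curve$youden), 0.5)
  expect_equal(r$sensitivity, 1)      # tie resolved to the lower threshold
  expect_equal(r$specificity, 0.5)
  expect_error(rocYouden(1:4, c(1, 1, 1, 1)), "degenerate",
               class = "msersArgumentError")
})

test_that("ROC optimum matches an exhaustive threshold scan", {
  set.seed(77)
  for (i in 1:100) {
    n <- sample(6:50, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n, mean = labels), 2)
    r <- rocYouden(scores, labels)
    # oracle: evaluate J at every cut the >= rule can realize
    cand <- c(-Inf, sort(unique(scores)), Inf)
    J <- vapply(cand, function(t) {
      call <- scores >= t
      sum(call & labels == 1) / sum(labels) +
        sum(!call & labels == 0) / sum(labels == 0) - 1
    }, numeric(1))
    expect_equal(r$sensitivity + r$specificity - 1, max(J), tolerance = 1e-12)
  }
})

test_that("ROC AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(11)
  for (i in 1:5) {
    labels <- sample(0:1, 40, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(labels)) < 2) next
    scores <- rnorm(40, labels)
    r <- rocYouden(scores, labels)
    ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
    expect_equal(r$auc, as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("confusion metrics follow the standard definitions", {
  perfect <- confusionMetrics(c(1, 1, 0), c(1, 1, 0), positive = "1")
  expect_equal(unlist(perfect), c(sensitivity = 1, specificity = 1, accuracy = 1))
  allPos <- confusionMetrics(rep(1, 99), c(rep(1, 48), rep(0, 51)),
                             positive = "1")
  expect_equal(allPos$sensitivity, 1)
  expect_equal(allPos$specificity, 0)
  expect_equal(allPos$accuracy, 48 / 99)
  set.seed(5)
  pred <- sample(0:1, 30, TRUE); act <- c(0, 1, sample(0:1, 28, TRUE))
  m <- confusionMetrics(pred, act, positive = "1")
  tp <- sum(pred == 1 & act == 1); tn <- sum(pred == 0 & act == 0)
  expect_equal(m$sensitivity, tp / sum(act == 1))
  expect_equal(m$specificity, tn / sum(act == 0))
  expect_equal(m$accuracy, (tp + tn) / 30)
})

test_that("Fisher's exact test matches full enumeration on 2x2 tables", {
  expect_equal(fisherExact(matrix(c(5, 5, 5, 5), 2)), 1.0)
  expect_equal(fisherExact(matrix(c(3, 1, 1, 3), 2)), 34 / 70,
               tolerance = 1e-10)
  expect_equal(fisherExact(matrix(c(3, 1, 1, 3), 2)),
               bruteFisher2x2(matrix(c(3, 1, 1, 3), 2)), tolerance = 1e-10)
  set.seed(21)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 5) + 1, 2)
    expect_equal(fisherExact(tab), bruteFisher2x2(tab), tolerance = 1e-10,
                 info = paste(tab, collapse = ","))
  }
})

test_that("Fisher's exact test validates input and its budget", {
  expect_error(fisherExact(matrix(c(0, 0, 1, 2), 2, byrow = TRUE)),
               "zero margin", class = "msersArgumentError")
  expect_error(fisherExact(matrix(c(1.5, 1, 1, 1), 2)),
               class = "msersArgumentError")
  expect_error(fisherExact(matrix(c(-1, 1, 1, 1), 2)),
               class = "msersArgumentError")
  expect_error(fisherExact(matrix(200, 3, 3)), class = "msersCapacityError")
  # r x c tables go through the same exact rule
  tab <- matrix(c(4, 1, 2, 2, 3, 5), 2)
  expect_equal(fisherExact(tab), stats::fisher.test(tab)$p.value)
})

test_that("CART separates a one-feature threshold problem at depth 1", {
  x <- data.frame(f = c(0.1, 0.2, 0.3, 0.6, 0.7, 0.9))
  y <- ifelse(x$f > 0.5, "pos", "neg")
  tree <- cartFit(x, y, minLeaf = 1L, maxDepth = 3L)
  expect_false(tree$leaf)
  expect_true(tree$left$leaf && tree$right$leaf)
  expect_equal(cartPredict(tree, x), y)
})

test_that("CART solves XOR at depth 2 and matches the root Gini oracle", {
  x <- data.frame(a = c(0, 0, 1, 1, 0, 0, 1, 1),
                  b = c(0, 1, 0, 1, 0, 1, 0, 1))
  y <- ifelse(xor(x$a, x$b), "one", "zero")
  tree <- cartFit(x, y, minLeaf = 1L, maxDepth = 2L)
  expect_equal(cartPredict(tree, x), y)

  # exhaustive Gini search over every feature and midpoint at the root
  gini <- function(lab) 1 - sum((table(lab) / length(lab))^2)
  exhaustiveRoot <- function(x, y) {
    best <- NULL
    for (j in seq_along(x)) {
      v <- sort(unique(x[[j]]))
      if (length(v) < 2) next
      for (t in (v[-1] + v[-length(v)]) / 2) {
        sel <- x[[j]] <= t
        g <- (sum(sel) * gini(y[sel]) + sum(!sel) * gini(y[!sel])) / length(y)
        if (is.null(best) || g < best$g - 1e-12)
          best <- list(g = g, feature = names(x)[j], threshold = t)
      }
    }
    best
  }
  set.seed(42)
  for (i in 1:20) {
    xr <- data.frame(u = rnorm(30), v = rnorm(30), w = sample(0:1, 30, TRUE))
    yr <- ifelse(xr$u + 0.5 * xr$w + rnorm(30, 0, 0.5) > 0, "cancer", "control")
    if (length(unique(yr)) < 2) next
    tr <- cartFit(xr, yr, minLeaf = 3L, maxDepth = 3L)
    if (tr$leaf) next
    oracle <- exhaustiveRoot(xr, yr)
    g <- (sum(xr[[tr$feature]] <= tr$threshold) *
            gini(yr[xr[[tr$feature]] <= tr$threshold]) +
          sum(xr[[tr$feature]] > tr$threshold) *
            gini(yr[xr[[tr$feature]] > tr$threshold])) / length(yr)
    expect_equal(g, oracle$g, tolerance = 1e-12)
    expect_equal(tr$feature, oracle$feature)
  }
})

test_that("CART stops on pure nodes and reaches 100% on separable data", {
  pure <- cartFit(data.frame(x = 1:10), rep("a", 10), minLeaf = 1L)
  expect_true(pure$leaf)
  set.seed(9)
  x <- data.frame(f1 = rnorm(40), f2 = rnorm(40))
  y <- ifelse(x$f1 + x$f2 > 0, "pos", "neg")   # separable by axis cuts at depth
  tree <- cartFit(x, y, minLeaf = 1L, maxDepth = 20L)
  expect_equal(mean(cartPredict(tree, x) == y), 1)
  expect_error(cartFit(data.frame(), c("a", "b")), class = "msersArgumentError")
  expect_error(cartFit(data.frame(x = c(1, NaN)), c("a", "b")),
               class = "msersArgumentError")
})

test_that("CART training accuracy matches rpart on a clean problem", {
  skip_if_not_installed("rpart")
  set.seed(13)
  x <- data.frame(f1 = rnorm(60), f2 = rnorm(60))
  y <- factor(ifelse(x$f1 > 0.2, "pos", "neg"))
  ours <- cartFit(x, as.character(y), minLeaf = 5L, maxDepth = 3L)
  ref <- rpart::rpart(y ~ ., data = cbind(x, y = y), method = "class",
                      control = rpart::rpart.control(minbucket = 5, minsplit = 10,
                                                     maxdepth = 3, cp = 0,
                                                     xval = 0))
  expect_equal(mean(cartPredict(ours, x) == as.character(y)),
               mean(predict(ref, x, type = "class") == y))
})

test_that("trees serialize to text and plain lists", {
  x <- data.frame(level_p16 = c(0.2, 0.3, 0.0, 0.01))
  tree <- cartFit(x, c("cancer", "cancer", "control", "control"), minLeaf = 1L)
  txt <- formatTree(tree)
  expect_true(any(grepl("level_p16", txt)))
  expect_true(any(grepl("predict", txt)))
  lst <- treeToList(tree)
  expect_false(lst$leaf)
  expect_true(lst$left$leaf)
  expect_type(jsonlite::toJSON(lst), "character")
})
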