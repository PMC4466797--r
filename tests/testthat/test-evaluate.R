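test_that("metrics reproduce hand-computed confusion summaries", {
  m <- metrics(confusionMatrix(tp = 9, tn = 90, fp = 10, fn = 1))
  expect_equal(m$sensitivity, 0.9)
  expect_equal(m$specificity, 0.9)
  expect_equal(m$accuracy, 99 / 110)
  expect_equal(m$g_mean, 0.9)
  # perfect classifier
  p <- metrics(confusionMatrix(tp = 5, tn = 5, fp = 0, fn = 0))
  expect_true(all(unlist(p) == 1))
})

test_that("empty class margins yield NA metrics, not zero", {
  m <- metrics(confusionMatrix(tp = 0, tn = 10, fp = 0, fn = 0))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$g_mean))
  expect_equal(m$specificity, 1)
  expect_error(metrics(confusionMatrix(0, 0, 0, 0)), "empty")
})

test_that("the G-mean is the geometric mean of sensitivity and specificity", {
  cm <- confusionMatrix(tp = 92, tn = 57215, fp = 14454, fn = 85)
  m <- metrics(cm)
  expect_equal(m$g_mean, sqrt(m$sensitivity * m$specificity), tolerance = 1e-12)
  # the product convention would give a visibly different value
  expect_gt(abs(m$g_mean - m$sensitivity * m$specificity), 0.2)
})

test_that("ROC/AUC handles the trivial ranking conventions", {
  lab <- c("active", "active", "inactive", "inactive")
  expect_equal(rocAuc(lab, c(1, 1, 0, 0))$auc, 1)
  expect_equal(rocAuc(lab, c(0.5, 0.5, 0.5, 0.5))$auc, 0.5)
  expect_equal(rocAuc(lab, c(0, 0, 1, 1))$auc, 0)
  expect_error(rocAuc(rep("active", 3), 1:3), "both classes")
})

test_that("AUC equals the exhaustive pairwise-concordance oracle", {
  # 6-point hand case: actives 0.9, 0.6; inactives 0.8, 0.4, 0.3, 0.2
  lab <- c("active", "active", rep("inactive", 4))
  sc <- c(0.9, 0.6, 0.8, 0.4, 0.3, 0.2)
  expect_equal(rocAuc(lab, sc)$auc, pairwiseAuc(lab, sc))  # 7/8
  expect_equal(rocAuc(lab, sc)$auc, 7 / 8)
  withSeed(19, {
    for (rep in 1:20) {
      n <- sample(10:60, 1)
      lab <- sample(c("active", "inactive"), n, replace = TRUE,
                    prob = c(0.3, 0.7))
      if (length(unique(lab)) < 2) next
      sc <- round(stats::rnorm(n), 1)   # coarse scores force ties
      expect_equal(rocAuc(lab, sc)$auc, pairwiseAuc(lab, sc),
                   tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an independent ROC library", {
  withSeed(23, {
    lab <- sample(c("active", "inactive"), 80, replace = TRUE)
    sc <- stats::rnorm(80) + (lab == "active")
    ours <- rocAuc(lab, sc)$auc
    ref <- as.numeric(pROC::auc(pROC::roc(
      response = lab, predictor = sc, levels = c("inactive", "active"),
      direction = "<", quiet = TRUE)))
    expect_equal(ours, ref, tolerance = 1e-12)
  })
})

test_that("the ROC curve starts at (0,0), ends at (1,1) and is monotone", {
  withSeed(31, {
    lab <- sample(c("active", "inactive"), 50, replace = TRUE)
    sc <- stats::rnorm(50)
    pts <- rocAuc(lab, sc)$points
    expect_equal(unlist(pts[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(pts[nrow(pts), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  })
})

test_that("stratified CV conserves counts and is reproducible", {
  toy <- overlapToy(n = 200)
  cv1 <- crossValidate("naive_bayes", toy$table, toy$labels, folds = 5,
                       seed = 17)
  cv2 <- crossValidate("naive_bayes", toy$table, toy$labels, folds = 5,
                       seed = 17)
  expect_identical(cv1$foldAssignment, cv2$foldAssignment)
  expect_identical(confusionCounts(cv1$pooled), confusionCounts(cv2$pooled))
  expect_equal(sum(confusionCounts(cv1$pooled)), 200)
  # pooled = elementwise sum of folds
  expect_equal(Reduce(`+`, lapply(cv1$perFold, confusionCounts)),
               confusionCounts(cv1$pooled))
  # stratification: every fold holds actives
  for (f in 1:5)
    expect_gt(sum(toy$labels[cv1$foldAssignment == f] == "active"), 0)
  # fold sizes balanced within 1
  expect_lte(diff(range(table(cv1$foldAssignment))), 2)
})

test_that("too few actives to stratify raises an informative error", {
  toy <- overlapToy(n = 40)
  lab <- toy$labels
  lab[lab == "active"] <- "inactive"
  lab[1:3] <- "active"
  expect_error(crossValidate("naive_bayes", toy$table, lab, folds = 5),
               "fewer folds")
  expect_error(crossValidate("naive_bayes", toy$table, toy$labels, folds = 1),
               ">= 2")
})

test_that("consensus is the intersection of per-model active sets", {
  expect_setequal(consensusActives(list(c("A", "B", "C"), c("B", "C"),
                                        c("B", "C", "D"))), c("B", "C"))
  expect_length(consensusActives(list(c("A"), character(0), c("A"))), 0)
  expect_identical(consensusActives(list(c("X", "Y"))), c("X", "Y"))
})

test_that("metric tables print in the tabulated column order", {
  path <- tempfile(fileext = ".tsv")
  df <- writeMetricTable(list(nb = confusionMatrix(9, 90, 10, 1)), path)
  expect_identical(names(df)[1:5], c("model", "tp", "tn", "fp", "fn"))
  back <- utils::read.delim(path)
  expect_equal(back$g_mean, 0.9)
  expect_equal(back$sensitivity_pct, 90)
})
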