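test_that("all three families separate a separable toy perfectly", {
  toy <- separableToy()
  for (fam in c("naive_bayes", "random_forest", "svm_smo_like")) {
    model <- trainCostModel(fam, toy$table, toy$labels, seed = 2)
    pred <- predictActivity(model, toy$table)
    expect_identical(pred$classes, toy$labels, label = fam)
  }
})

test_that("naive Bayes posterior matches the hand-smoothed value", {
  # 4 rows, one binary feature x: actives (1, 0), inactives (1, 1)
  # alpha = 1: P(x=1|act) = 2/4, P(x=1|inact) = 3/4, priors 1/2
  # posterior(active | x=1) = .5*.5 / (.5*.5 + .5*.75) = 0.4
  tab <- cbind(x = c(1, 0, 1, 1))
  lab <- c("active", "active", "inactive", "inactive")
  model <- trainCostModel("naive_bayes", tab, lab, seed = 1)
  pred <- predictActivity(model, cbind(x = c(1, 0)))
  expect_equal(unname(pred$scores[1]), 0.4, tolerance = 1e-12)
  # posterior(active | x=0) = .5*.5 / (.5*.5 + .5*.25) = 2/3
  expect_equal(unname(pred$scores[2]), 2 / 3, tolerance = 1e-12)
})

test_that("FN-cost weighting equals replicating active rows (naive Bayes)", {
  toy <- overlapToy(n = 80)
  k <- 3
  mW <- trainCostModel("naive_bayes", toy$table, toy$labels, costFn = k,
                       seed = 1)
  actives <- which(toy$labels == "active")
  repIdx <- c(rep(actives, k), which(toy$labels == "inactive"))
  mR <- trainCostModel("naive_bayes", toy$table[repIdx, ],
                       toy$labels[repIdx], costFn = 1, seed = 1)
  pred <- predictActivity(mW, toy$table)
  predR <- predictActivity(mR, toy$table)
  expect_equal(pred$scores, predR$scores, tolerance = 1e-12)
  expect_identical(pred$classes, predR$classes)
})

test_that("raising the FN cost trades specificity for sensitivity", {
  toy <- overlapToy(n = 400, shift = 1.0)
  sn <- sp <- numeric(0)
  for (cost in c(1, 4, 16)) {
    cv <- crossValidate("naive_bayes", toy$table, toy$labels, folds = 5,
                        seed = 3, costFn = cost)
    m <- metrics(cv$pooled)
    sn <- c(sn, m$sensitivity); sp <- c(sp, m$specificity)
  }
  expect_true(all(diff(sn) >= -1e-9))
  expect_true(all(diff(sp) <= 1e-9))
})

test_that("training and prediction validate their inputs", {
  toy <- separableToy()
  expect_error(trainCostModel("naive_bayes", toy$table,
                              rep("active", nrow(toy$table))),
               "degenerate")
  bad <- toy$table; bad[1, 1] <- NA
  expect_error(trainCostModel("naive_bayes", bad, toy$labels), "missing")
  model <- trainCostModel("naive_bayes", toy$table, toy$labels)
  expect_error(predictActivity(model, toy$table[, "f1", drop = FALSE]),
               "schema mismatch")
  renamed <- toy$table; colnames(renamed) <- c("f1", "other")
  expect_error(predictActivity(model, renamed), "other")
})

test_that("prediction commutes with row permutation and is row-wise pure", {
  toy <- overlapToy(n = 60)
  model <- trainCostModel("random_forest", toy$table, toy$labels, seed = 4)
  perm <- sample(nrow(toy$table))
  p1 <- predictActivity(model, toy$table)
  p2 <- predictActivity(model, toy$table[perm, ])
  expect_equal(unname(p2$scores), unname(p1$scores[perm]), tolerance = 1e-12)
  same <- toy$table[rep(1, 5), ]
  p3 <- predictActivity(model, same)
  expect_true(all(p3$scores == p3$scores[1]))
})

test_that("tuneFnCost brackets the FP ceiling against a linear-scan oracle", {
  toy <- overlapToy(n = 300, shift = 1.0)
  res <- tuneFnCost("naive_bayes", toy$table, toy$labels, fp_ceiling = 0.2,
                    folds = 5, seed = 5)
  fpAt <- function(cost) {
    cm <- crossValidate("naive_bayes", toy$table, toy$labels, folds = 5,
                        seed = 5, costFn = cost)$pooled
    cm@fp / (cm@fp + cm@tn)
  }
  expect_false(res$ceiling_unreachable)
  expect_lte(res$fp_rate, 0.2)
  expect_equal(res$fp_rate, fpAt(res$c_fn), tolerance = 1e-12)
  expect_gt(fpAt(res$c_fn + 1), 0.2)   # the next cost unit crosses
  # linear scan agrees that every cost up to the chosen one stays under
  expect_gt(res$c_fn, 1)
})

test_that("a looser ceiling never chooses a smaller cost", {
  toy <- overlapToy(n = 300, shift = 1.0)
  tight <- tuneFnCost("naive_bayes", toy$table, toy$labels,
                      fp_ceiling = 0.2, folds = 5, seed = 5)
  loose <- tuneFnCost("naive_bayes", toy$table, toy$labels,
                      fp_ceiling = 0.5, folds = 5, seed = 5)
  expect_gte(loose$c_fn, tight$c_fn)
})

test_that("perfectly separable data needs no cost escalation", {
  toy <- separableToy(n = 60)
  res <- tuneFnCost("naive_bayes", toy$table, toy$labels, folds = 5, seed = 1)
  expect_identical(res$c_fn, 1)
  expect_equal(res$fp_rate, 0)
})

test_that("an unreachable ceiling flags and returns cost 1", {
  # classes nearly indistinguishable and prevalence high: FP rate high at c=1
  withSeed(77, {
    n <- 200
    lab <- rep(c("active", "inactive"), n / 2)
    vals <- cbind(f1 = stats::rnorm(n) +
                    0.3 * (lab == "active"))
    expect_warning(
      res <- tuneFnCost("naive_bayes", vals, lab, fp_ceiling = 0.05,
                        folds = 5, seed = 2),
      "ceiling")
    expect_true(res$ceiling_unreachable)
    expect_identical(res$c_fn, 1)
  })
})
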