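# Confusion-matrix metrics, ROC/AUC, stratified cross-validation, consensus.

#' Confusion matrix from predicted and true labels
#' @param predicted,truth `"active"`/`"inactive"` vectors of equal length.
#' @return a [ConfusionMatrix-class].
#' @export
confusionFromLabels <- function(predicted, truth) {
  predicted <- normalizeLabels(predicted); truth <- normalizeLabels(truth)
  stopifnot(length(predicted) == length(truth))
  confusionMatrix(tp = sum(predicted == "active" & truth == "active"),
                  tn = sum(predicted == "inactive" & truth == "inactive"),
                  fp = sum(predicted == "active" & truth == "inactive"),
                  fn = sum(predicted == "inactive" & truth == "active"))
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, accuracy
#' `(TP+TN)/total` and the G-mean `sqrt(sensitivity * specificity)` -- the
#' geometric mean, the balanced summary used for heavily imbalanced screens.
#' A metric whose margin is empty (e.g. sensitivity with no actives) is
#' `NA`, not 0.
#'
#' @param cm a [ConfusionMatrix-class].
#' @return list with `sensitivity`, `specificity`, `accuracy`, `g_mean`
#'   (proportions in `[0, 1]`).
#' @examples
#' metrics(confusionMatrix(tp = 92, tn = 57215, fp = 14454, fn = 85))
#' @export
metrics <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  total <- cm@tp + cm@tn + cm@fp + cm@fn
  if (total == 0) stop("empty confusion matrix")
  sn <- if (cm@tp + cm@fn > 0) cm@tp / (cm@tp + cm@fn) else NA_real_
  sp <- if (cm@tn + cm@fp > 0) cm@tn / (cm@tn + cm@fp) else NA_real_
  list(sensitivity = sn, specificity = sp,
       accuracy = (cm@tp + cm@tn) / total,
       g_mean = sqrt(sn * sp))
}

#' Format a metric report as percentages
#'
#' Percentages to one decimal (round-half-even, R's default rounding);
#' G-mean to two decimals.
#' @param m result of [metrics()].
#' @return named numeric vector
#'   (`sensitivity_pct`, `specificity_pct`, `accuracy_pct`, `g_mean`).
#' @export
formatMetrics <- function(m) {
  c(sensitivity_pct = round(100 * m$sensitivity, 1),
    specificity_pct = round(100 * m$specificity, 1),
    accuracy_pct = round(100 * m$accuracy, 1),
    g_mean = round(m$g_mean, 2))
}

#' ROC curve and AUC
#'
#' AUC by trapezoidal integration over all score thresholds, equal to the
#' Mann-Whitney concordance probability with ties counted 1/2.
#'
#' @param labels `"active"`/`"inactive"` per observation (both classes
#'   required).
#' @param scores numeric scores, higher = more active.
#' @return list with `points` (data.frame `fpr`, `tpr`, threshold-ordered)
#'   and `auc`.
#' @export
rocAuc <- function(labels, scores) {
  labels <- normalizeLabels(labels)
  stopifnot(length(labels) == length(scores), all(is.finite(scores)))
  nA <- sum(labels == "active"); nI <- sum(labels == "inactive")
  if (nA == 0 || nI == 0) stop("both classes must be present")
  # Mann-Whitney via midranks (ties counted 1/2)
  r <- rank(scores, ties.method = "average")
  auc <- (sum(r[labels == "active"]) - nA * (nA + 1) / 2) / (nA * nI)
  # curve: sweep thresholds from +Inf downwards
  ord <- order(scores, decreasing = TRUE)
  tpCum <- cumsum(labels[ord] == "active")
  fpCum <- cumsum(labels[ord] == "inactive")
  # one point per distinct threshold (last position of each tied block)
  cut <- sort(unique(c(which(diff(scores[ord]) != 0), length(ord))))
  points <- data.frame(fpr = c(0, fpCum[cut] / nI), tpr = c(0, tpCum[cut] / nA))
  list(points = points, auc = auc)
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class so every fold keeps actives even at
#' sub-percent prevalence; assignment is deterministic for a fixed seed. The
#' pooled confusion matrix is the elementwise sum over folds.
#'
#' @param family learner family (see [trainCostModel()]).
#' @param table descriptor table.
#' @param labels `"active"`/`"inactive"` per row.
#' @param folds number of folds (>= 2).
#' @param seed integer seed.
#' @param costFn false-negative cost used for each fold's model.
#' @return list with `pooled` ([ConfusionMatrix-class]), `perFold` (list of
#'   [ConfusionMatrix-class]), `foldAssignment` (integer vector) and `scores`
#'   (out-of-fold scores, one per row).
#' @export
crossValidate <- function(family, table, labels, folds = 5, seed = 1L,
                          costFn = 1) {
  labels <- normalizeLabels(labels)
  vals <- tableValues(table)
  n <- nrow(vals)
  stopifnot(length(labels) == n)
  if (folds < 2) stop("folds must be >= 2")
  nA <- sum(labels == "active")
  if (nA < folds)
    stop("too few actives (", nA, ") to stratify into ", folds,
         " folds; use fewer folds")
  assign <- integer(n)
  withSeed(seed, {
    for (cl in c("active", "inactive")) {
      idx <- which(labels == cl)
      assign[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  perFold <- vector("list", folds)
  scores <- numeric(n)
  classes <- character(n)
  subsetRows <- function(tab, sel)
    if (is.matrix(tab)) tab[sel, , drop = FALSE] else tab[sel, ]
  for (f in seq_len(folds)) {
    test <- assign == f
    model <- trainCostModel(family, subsetRows(table, !test), labels[!test],
                            costFn = costFn, seed = childSeed(seed, f))
    pred <- predictActivity(model, subsetRows(table, test))
    perFold[[f]] <- confusionFromLabels(pred$classes, labels[test])
    scores[test] <- pred$scores
    classes[test] <- pred$classes
  }
  counts <- Reduce(`+`, lapply(perFold, confusionCounts))
  list(pooled = confusionMatrix(counts["tp"], counts["tn"], counts["fp"],
                                counts["fn"]),
       perFold = perFold, foldAssignment = assign, scores = scores,
       classes = classes)
}

#' Consensus actives across models
#'
#' The intersection of per-model active sets: a compound is a consensus
#' active only if every model predicts it active.
#'
#' @param activeSets list (>= 1) of character vectors of compound ids.
#' @return character vector of consensus ids.
#' @examples
#' consensusActives(list(c("A", "B", "C"), c("B", "C"), c("B", "C", "D")))
#' @export
consensusActives <- function(activeSets) {
  stopifnot(is.list(activeSets), length(activeSets) >= 1)
  Reduce(intersect, activeSets)
}

#' Write a metric table (tab-separated, one model per row)
#'
#' Columns: model, TP, TN, FP, FN, sensitivity %, specificity %, accuracy %,
#' G-mean.
#' @param rows named list: model name -> [ConfusionMatrix-class].
#' @param path output file.
#' @return the data.frame, invisibly.
#' @export
writeMetricTable <- function(rows, path) {
  df <- do.call(rbind, lapply(names(rows), function(nm) {
    cm <- rows[[nm]]
    m <- formatMetrics(metrics(cm))
    data.frame(model = nm, tp = cm@tp, tn = cm@tn, fp = cm@fp, fn = cm@fn,
               sensitivity_pct = m["sensitivity_pct"],
               specificity_pct = m["specificity_pct"],
               accuracy_pct = m["accuracy_pct"], g_mean = m["g_mean"],
               row.names = NULL)
  }))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
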