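# Cost-sensitive classification. Three learner families:
#   naive_bayes   - native weighted naive Bayes (Bernoulli bits, Gaussian
#                   continuous, Laplace alpha = 1)
#   random_forest - ranger, honouring instance weights
#   svm_smo_like  - linear-kernel SVM (e1071) with logistic score calibration
# Cost sensitivity is uniform across families: every active training row
# carries instance weight c_fn, every inactive row weight 1.

.learnerFamilies <- c("naive_bayes", "random_forest", "svm_smo_like")

tableValues <- function(table) {
  if (is(table, "DescriptorTable")) descriptorValues(table) else as.matrix(table)
}

tableSchema <- function(table) {
  if (is(table, "DescriptorTable")) return(descriptorSchema(table))
  vals <- as.matrix(table)
  isBin <- apply(vals, 2, function(v) all(v %in% c(0, 1)))
  data.frame(name = colnames(vals), family = "unknown",
             dtype = ifelse(isBin, "binary", "continuous"))
}

checkTraining <- function(vals, labels) {
  if (anyNA(vals)) stop("missing values in the descriptor table")
  if (length(unique(labels)) < 2)
    stop("degenerate training data: only one class present")
  if (is.null(colnames(vals))) stop("descriptor columns must be named")
}

# ---- native weighted naive Bayes ----

nbFit <- function(vals, labels, w, dtype) {
  fit <- list(dtype = dtype, classes = c("active", "inactive"))
  for (cl in fit$classes) {
    sel <- labels == cl
    wc <- w[sel]
    sw <- sum(wc)
    fit[[cl]] <- list(
      prior = sw / sum(w),
      # Bernoulli with Laplace alpha = 1
      p1 = (colSums(vals[sel, dtype == "binary", drop = FALSE] * wc) + 1) / (sw + 2),
      mu = colSums(vals[sel, dtype == "continuous", drop = FALSE] * wc) / sw,
      var = {
        x <- vals[sel, dtype == "continuous", drop = FALSE]
        mu <- colSums(x * wc) / sw
        pmax(colSums((x - rep(mu, each = nrow(x)))^2 * wc) / sw, 1e-9)
      })
  }
  fit
}

nbLogLik <- function(fit, vals, cl) {
  par <- fit[[cl]]
  ll <- rep(log(par$prior), nrow(vals))
  bin <- names(par$p1)
  if (length(bin)) {
    x <- vals[, bin, drop = FALSE]
    ll <- ll + as.numeric(x %*% log(par$p1) + (1 - x) %*% log(1 - par$p1))
  }
  cont <- names(par$mu)
  if (length(cont)) {
    x <- vals[, cont, drop = FALSE]
    for (j in seq_along(cont))
      ll <- ll + stats::dnorm(x[, j], par$mu[j], sqrt(par$var[j]), log = TRUE)
  }
  ll
}

nbPredict <- function(fit, vals) {
  la <- nbLogLik(fit, vals, "active")
  li <- nbLogLik(fit, vals, "inactive")
  post <- 1 / (1 + exp(li - la))
  list(classes = ifelse(la >= li, "active", "inactive"), scores = post)
}

# ---- training front-end ----

#' Train a cost-sensitive classifier
#'
#' @param family one of `"naive_bayes"`, `"random_forest"`, `"svm_smo_like"`.
#' @param table a [DescriptorTable-class] or numeric matrix with named
#'   columns.
#' @param labels `"active"`/`"inactive"` per row.
#' @param costFn false-negative cost (>= 1): the instance weight given to
#'   every active training row (inactives get 1). The false-positive cost is
#'   fixed at 1.
#' @param seed integer seed for stochastic learners.
#' @return a [CostModel-class].
#' @export
trainCostModel <- function(family = .learnerFamilies, table, labels,
                           costFn = 1, seed = 1L) {
  family <- match.arg(family)
  vals <- tableValues(table)
  schema <- tableSchema(table)
  labels <- normalizeLabels(labels)
  stopifnot(nrow(vals) == length(labels), costFn >= 1)
  checkTraining(vals, labels)
  w <- ifelse(labels == "active", costFn, 1)
  fit <- withSeed(seed, switch(family,
    naive_bayes = nbFit(vals, labels, w, schema$dtype),
    random_forest = {
      y <- factor(labels, levels = c("active", "inactive"))
      rf <- ranger::ranger(x = as.data.frame(vals), y = y,
                           num.trees = 200, probability = TRUE,
                           case.weights = w, seed = seed, num.threads = 1)
      list(rf = rf)
    },
    svm_smo_like = {
      y <- factor(labels, levels = c("active", "inactive"))
      # standardize internally (libsvm converges poorly on raw magnitudes);
      # zero-variance columns get scale 1
      ctr <- colMeans(vals)
      scl <- apply(vals, 2, stats::sd); scl[scl == 0 | !is.finite(scl)] <- 1
      sval <- scale(vals, center = ctr, scale = scl)
      sv <- e1071::svm(x = sval, y = y, kernel = "linear", scale = FALSE,
                       class.weights = c(active = costFn, inactive = 1))
      dv <- attr(stats::predict(sv, sval, decision.values = TRUE),
                 "decision.values")[, 1]
      cal <- suppressWarnings(stats::glm.fit(
        x = cbind(1, dv), y = as.integer(labels == "active"),
        family = stats::binomial()))
      list(sv = sv, calib = cal$coefficients, center = ctr, scale = scl)
    }))
  new("CostModel", family = family, costFn = costFn, fit = fit,
      schema = schema, seed = as.integer(seed))
}

#' Predict classes and activity scores
#'
#' @param model a [CostModel-class].
#' @param table descriptor table whose columns match the training schema
#'   (order-insensitive; missing or extra columns are an error).
#' @return list with `classes` (`"active"`/`"inactive"`) and `scores`
#'   (higher = more active, usable for ROC).
#' @export
predictActivity <- function(model, table) {
  stopifnot(is(model, "CostModel"))
  vals <- tableValues(table)
  want <- model@schema$name
  have <- colnames(vals)
  missing <- setdiff(want, have); extra <- setdiff(have, want)
  if (length(missing) || length(extra))
    stop("descriptor schema mismatch; missing: [",
         paste(missing, collapse = ", "), "] extra: [",
         paste(extra, collapse = ", "), "]")
  vals <- vals[, want, drop = FALSE]
  out <- switch(model@family,
    naive_bayes = nbPredict(model@fit, vals),
    random_forest = {
      pr <- stats::predict(model@fit$rf, data = as.data.frame(vals),
                           num.threads = 1)$predictions[, "active"]
      list(classes = ifelse(pr >= 0.5, "active", "inactive"), scores = pr)
    },
    svm_smo_like = {
      sval <- scale(vals, center = model@fit$center, scale = model@fit$scale)
      pc <- stats::predict(model@fit$sv, sval, decision.values = TRUE)
      dv <- attr(pc, "decision.values")[, 1]
      b <- model@fit$calib
      list(classes = as.character(pc),
           scores = stats::plogis(b[1] + b[2] * dv))
    })
  names(out$scores) <- rownames(vals)
  out
}

#' @describeIn predictActivity method so that `predict(model, table)` works.
#' @param object a [CostModel-class].
#' @param ... passed through (`table`).
#' @export
setMethod("predict", "CostModel",
          function(object, ...) predictActivity(object, ...))

# ---- FN-cost escalation against a false-positive-rate ceiling ----

#' Tune the false-negative cost against a false-positive-rate ceiling
#'
#' Evaluates the cross-validated false-positive rate `FP / (FP + TN)` over an
#' escalating FN-cost schedule: geometric doubling from 1 until the ceiling
#' is crossed, then bisection down to a resolution of one cost unit. Returns
#' the largest integer cost whose CV FP rate stays at or below the ceiling,
#' the model refit on all data at that cost, and the pooled CV confusion
#' matrix.
#'
#' @param family learner family (see [trainCostModel()]).
#' @param table descriptor table.
#' @param labels `"active"`/`"inactive"` per row.
#' @param fp_ceiling FP-rate ceiling in (0, 1); default 0.20.
#' @param folds stratified CV folds (default 5).
#' @param seed integer seed (CV splits and stochastic learners).
#' @param max_cost cap on the escalation (default 4096).
#' @return list with `model` ([CostModel-class]), `c_fn`, `cv_confusion`
#'   ([ConfusionMatrix-class] at the chosen cost), `fp_rate`, and
#'   `ceiling_unreachable` (TRUE when the FP rate already exceeds the ceiling
#'   at cost 1, in which case cost 1 is returned with a warning).
#' @export
tuneFnCost <- function(family, table, labels, fp_ceiling = 0.2, folds = 5,
                       seed = 1L, max_cost = 4096) {
  stopifnot(fp_ceiling > 0, fp_ceiling < 1)
  labels <- normalizeLabels(labels)
  evalCost <- function(costFn) {
    cv <- crossValidate(family, table, labels, folds = folds, seed = seed,
                        costFn = costFn)
    cm <- cv$pooled
    list(cm = cm, fp = cm@fp / (cm@fp + cm@tn))
  }
  e1 <- evalCost(1)
  if (e1$fp <= fp_ceiling && e1$cm@fn == 0) {
    # nothing left to recover: raising the FN cost cannot change the solution
    model <- trainCostModel(family, table, labels, costFn = 1, seed = seed)
    return(list(model = model, c_fn = 1, cv_confusion = e1$cm,
                fp_rate = e1$fp, ceiling_unreachable = FALSE))
  }
  if (e1$fp > fp_ceiling) {
    warning("FP rate exceeds the ceiling already at cost 1 (",
            signif(e1$fp, 3), " > ", fp_ceiling, ")")
    model <- trainCostModel(family, table, labels, costFn = 1, seed = seed)
    return(list(model = model, c_fn = 1, cv_confusion = e1$cm,
                fp_rate = e1$fp, ceiling_unreachable = TRUE))
  }
  lo <- 1; eLo <- e1; hi <- NA
  cost <- 2
  while (cost <= max_cost) {
    e <- evalCost(cost)
    if (e$fp > fp_ceiling) { hi <- cost; break }
    lo <- cost; eLo <- e
    cost <- cost * 2
  }
  if (!is.na(hi)) {
    while (hi - lo > 1) {
      mid <- floor((lo + hi) / 2)
      e <- evalCost(mid)
      if (e$fp > fp_ceiling) hi <- mid else { lo <- mid; eLo <- e }
    }
  }
  model <- trainCostModel(family, table, labels, costFn = lo, seed = seed)
  list(model = model, c_fn = lo, cv_confusion = eLo$cm, fp_rate = eLo$fp,
       ceiling_unreachable = FALSE)
}
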