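# Correlation-based feature-subset selection (CFS) searched by best-first
# with backtracking. The subset merit
#     merit(S) = k * mean(r_cf) / sqrt(k + k*(k-1) * mean(r_ff))
# rewards features correlated with the class (r_cf) and penalizes
# inter-correlated features (r_ff); both correlations are measured by
# symmetric uncertainty on discretized attributes.

#' Equal-frequency discretization
#'
#' Bins a continuous attribute into at most `bins` classes with (as far as
#' ties allow) equal occupancy. Attributes with few distinct values are left
#' as those values.
#'
#' @param x numeric vector.
#' @param bins maximum number of bins (default 10).
#' @return integer factor codes.
#' @export
discretizeEqualFreq <- function(x, bins = 10) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1),
                               type = 1))
  as.integer(cut(x, breaks = qs, include.lowest = TRUE))
}

#' Symmetric uncertainty between two discretized attributes
#'
#' `2 * I(x;y) / (H(x) + H(y))`, in `[0, 1]`; 0 by convention when either
#' marginal entropy is zero. Entropies in nats (the ratio is base-free).
#'
#' @param x,y equal-length vectors of discrete codes.
#' @return symmetric uncertainty in `[0, 1]`.
#' @examples
#' symmetricUncertainty(c(0, 0, 1, 1), c(0, 0, 1, 1))  # 1
#' @export
symmetricUncertainty <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  joint <- table(x, y)
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  ent <- function(q) { q <- q[q > 0]; -sum(q * log(q)) }
  hx <- ent(px); hy <- ent(py)
  if (hx == 0 || hy == 0) return(0)
  mi <- hx + hy - ent(as.vector(p))
  max(0, min(1, 2 * mi / (hx + hy)))
}

# Precompute discretized columns plus feature-class SU and (lazily) the
# feature-feature SU matrix for a descriptor table.
cfsPrepare <- function(table, labels, bins = 10) {
  vals <- if (is(table, "DescriptorTable")) descriptorValues(table) else as.matrix(table)
  labels <- normalizeLabels(labels)
  stopifnot(nrow(vals) == length(labels))
  disc <- apply(vals, 2, discretizeEqualFreq, bins = bins)
  y <- match(labels, c("inactive", "active"))
  rcf <- apply(disc, 2, symmetricUncertainty, y = y)
  env <- new.env(parent = emptyenv())
  env$disc <- disc
  env$rcf <- rcf
  env$rff <- matrix(NA_real_, ncol(disc), ncol(disc),
                    dimnames = list(colnames(disc), colnames(disc)))
  env$names <- colnames(vals)
  env
}

cfsRff <- function(prep, i, j) {
  v <- prep$rff[i, j]
  if (is.na(v)) {
    v <- symmetricUncertainty(prep$disc[, i], prep$disc[, j])
    prep$rff[i, j] <- prep$rff[j, i] <- v
  }
  v
}

cfsMeritIdx <- function(prep, idx) {
  k <- length(idx)
  if (k == 0)
    return(list(merit = 0, r_cf_mean = NA_real_, r_ff_mean = NA_real_, k = 0L))
  rcf <- mean(prep$rcf[idx])
  rff <- if (k == 1) 0 else {
    s <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      s <- s + cfsRff(prep, idx[a], idx[b])
    s / (k * (k - 1) / 2)
  }
  denom <- sqrt(k + k * (k - 1) * rff)
  list(merit = k * rcf / denom, r_cf_mean = rcf, r_ff_mean = rff, k = k)
}

#' CFS merit of a feature subset
#'
#' @param subset character vector of descriptor names (possibly empty).
#' @param table a [DescriptorTable-class] or numeric matrix with column names.
#' @param labels `"active"`/`"inactive"` per row.
#' @param prep optional precomputed state from internal preparation (used by
#'   the search); normally omitted.
#' @return list with `subset` (sorted), `merit`, `r_cf_mean`, `r_ff_mean`,
#'   `k`.
#' @export
cfsMerit <- function(subset, table, labels, prep = NULL) {
  prep <- prep %||% cfsPrepare(table, labels)
  idx <- match(subset, prep$names)
  if (anyNA(idx)) stop("unknown column(s): ",
                       paste(subset[is.na(idx)], collapse = ", "))
  res <- cfsMeritIdx(prep, idx)
  c(list(subset = sort(subset)), res)
}

subsetKey <- function(idx) paste0("s", paste(sort(idx), collapse = ","))

#' Best-first subset search over CFS merit
#'
#' Maintains a priority queue of evaluated subsets keyed by merit, repeatedly
#' expands the best unexpanded subset by single-feature additions (forward),
#' deletions (backward) or both (bidirectional), and stops after
#' `stale_limit` consecutive expansions without improving the global best.
#' Ties are broken lexicographically on the sorted column-name list, making
#' the search deterministic.
#'
#' @param table a [DescriptorTable-class] or numeric matrix with column names.
#' @param labels `"active"`/`"inactive"` per row.
#' @param direction `"forward"` (default, from the empty set), `"backward"`
#'   (from the full set) or `"bidirectional"`.
#' @param stale_limit non-improving expansions tolerated before termination
#'   (default 5).
#' @param bins discretization bins for continuous columns.
#' @return as [cfsMerit()], for the best subset found.
#' @export
bestFirstSearch <- function(table, labels,
                            direction = c("forward", "backward", "bidirectional"),
                            stale_limit = 5, bins = 10) {
  direction <- match.arg(direction)
  prep <- cfsPrepare(table, labels, bins = bins)
  p <- length(prep$names)
  if (p < 1) stop("need at least one candidate column")

  start <- switch(direction, forward = integer(0), backward = seq_len(p),
                  bidirectional = integer(0))
  evaluated <- new.env(parent = emptyenv())   # key -> merit
  queue <- list(list(idx = start, merit = cfsMeritIdx(prep, start)$merit))
  assign(subsetKey(start), queue[[1]]$merit, envir = evaluated)
  best <- queue[[1]]
  stale <- 0L

  lexKey <- function(idx) paste(sprintf("%06d", sort(idx)), collapse = ".")

  while (length(queue) > 0 && stale <= stale_limit) {
    merits <- vapply(queue, `[[`, numeric(1), "merit")
    ord <- order(-merits, vapply(queue, function(q) lexKey(q$idx), character(1)))
    node <- queue[[ord[1]]]
    queue <- queue[-ord[1]]

    children <- list()
    if (direction %in% c("forward", "bidirectional"))
      for (f in setdiff(seq_len(p), node$idx))
        children <- c(children, list(sort(c(node$idx, f))))
    if (direction %in% c("backward", "bidirectional"))
      for (f in node$idx)
        children <- c(children, list(setdiff(node$idx, f)))

    improved <- FALSE
    for (ch in children) {
      key <- subsetKey(ch)
      if (!is.null(evaluated[[key]])) next
      m <- cfsMeritIdx(prep, ch)$merit
      assign(key, m, envir = evaluated)
      queue <- c(queue, list(list(idx = ch, merit = m)))
      better <- m > best$merit + 1e-12 ||
        (abs(m - best$merit) <= 1e-12 && length(ch) > 0 &&
         lexKey(ch) < lexKey(best$idx))
      if (m > best$merit + 1e-12) improved <- TRUE
      if (better) best <- list(idx = ch, merit = m)
    }
    stale <- if (improved) 0L else stale + 1L
    if (stale_limit == 0) break   # degenerate limit: a single expansion
  }

  res <- cfsMeritIdx(prep, best$idx)
  c(list(subset = sort(prep$names[best$idx])), res)
}

#' Write a selected-descriptor list (one name per line)
#' @param subset character vector of descriptor names.
#' @param path output file.
#' @export
writeSelectedDescriptors <- function(subset, path) {
  writeLines(subset, path)
  invisible(path)
}

#' Read a selected-descriptor list
#' @param path input file.
#' @return character vector.
#' @export
readSelectedDescriptors <- function(path) {
  x <- readLines(path, warn = FALSE)
  x[nzchar(trimws(x))]
}
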