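# Shared fixtures, built in code and cached across test files within a run.

.fx <- new.env(parent = emptyenv())

# A small probe set of well-understood molecules.
probeCompounds <- function() {
  if (is.null(.fx$probe))
    .fx$probe <- parseCompounds(c(
      benzene = "c1ccccc1", ethanol = "CCO", water = "O", methane = "C",
      propane = "CCC", cyclopropane = "C1CC1", ethane = "CC",
      aceticAcid = "CC(=O)O", benzoquinone = "O=C1C=CC(=O)C=C1",
      acetateSalt = "CC(=O)[O-].[Na+]", aniline = "c1ccccc1N",
      nitroglycerinLike = "C(CO[N+](=O)[O-])O[N+](=O)[O-]"))
  .fx$probe
}

# A small enriched library shared by several module tests.
testLibrary <- function() {
  if (is.null(.fx$lib)) {
    .fx$lib <- generateLibrary(librarySpec(
      500, active_fraction = 0.1,
      enriched_fragments = c("Carboxylic acid" = 8), noise_sd = 5,
      seed = 101L))
    .fx$lab <- labelActivity(.fx$lib$assay$percent_inhibition)$activity_class
  }
  list(lib = .fx$lib, labels = .fx$lab)
}

# Descriptor table of the shared library (the slowest fixture; built once).
testDescriptors <- function() {
  if (is.null(.fx$desc)) {
    tl <- testLibrary()
    .fx$desc <- descriptorTable(tl$lib$compounds)
  }
  .fx$desc
}

# A separable two-feature toy set: actives high on f1, inactives low.
separableToy <- function(n = 40, seed = 5) {
  withSeed(seed, {
    lab <- rep(c("active", "inactive"), each = n / 2)
    f1 <- ifelse(lab == "active", 5, -5) + stats::rnorm(n, 0, 0.3)
    f2 <- stats::rnorm(n)
    list(table = cbind(f1 = f1, f2 = f2), labels = lab)
  })
}

# Overlapping two-class toy with a weak and a strong feature.
overlapToy <- function(n = 300, seed = 9, shift = 1.2, activeFrac = 0.25) {
  withSeed(seed, {
    nA <- round(n * activeFrac)
    lab <- c(rep("active", nA), rep("inactive", n - nA))
    f1 <- stats::rnorm(n) + ifelse(lab == "active", shift, 0)
    f2 <- stats::rnorm(n) + ifelse(lab == "active", shift / 2, 0)
    b1 <- as.integer(stats::runif(n) < ifelse(lab == "active", 0.6, 0.25))
    list(table = cbind(f1 = f1, f2 = f2, b1 = b1), labels = lab)
  })
}

# Random synthetic table for CFS search-vs-exhaustive comparisons:
# a couple of informative features plus noise.
randomCfsTable <- function(p, n = 60, seed = 1) {
  withSeed(seed, {
    lab <- rep(c("active", "inactive"), length.out = n)
    nInf <- sample(1:3, 1)
    vals <- sapply(seq_len(p), function(j) {
      if (j <= nInf) {
        flip <- stats::runif(n) < stats::runif(1, 0.05, 0.4)
        x <- as.integer(lab == "active")
        ifelse(flip, 1L - x, x)
      } else sample(0:1, n, replace = TRUE)
    })
    colnames(vals) <- sprintf("f%02d", seq_len(p))
    list(table = vals, labels = lab)
  })
}

# Brute-force exhaustive CFS oracle over all non-empty subsets.
exhaustiveBestMerit <- function(table, labels) {
  prep <- BioassayTriage:::cfsPrepare(table, labels)
  p <- ncol(table)
  for (i in seq_len(p - 1)) for (j in (i + 1):p) BioassayTriage:::cfsRff(prep, i, j)
  best <- 0
  for (mask in seq_len(2^p - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1, seq_len(p) - 1)) > 0)
    m <- BioassayTriage:::cfsMeritIdx(prep, idx)$merit
    if (m > best) best <- m
  }
  best
}

# Exhaustive pairwise-concordance AUC oracle (ties count 1/2).
pairwiseAuc <- function(labels, scores) {
  a <- scores[labels == "active"]; i <- scores[labels == "inactive"]
  s <- 0
  for (x in a) for (y in i) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(a) * length(i))
}

# Two-sided Fisher p-value by direct hypergeometric summation.
hypergeomTwoSided <- function(x, m, n, k) {
  # x successes drawn, m successes total, n failures total, k drawn
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  pObs <- stats::dhyper(x, m, n, k)
  sum(probs[probs <= pObs * (1 + 1e-7)])
}
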