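test_that("symmetric uncertainty hits its anchor values", {
  expect_equal(symmetricUncertainty(c(0, 0, 1, 1), c(0, 0, 1, 1)), 1)
  expect_equal(symmetricUncertainty(c(0, 0, 1, 1), c(1, 1, 0, 0)), 1)
  # exact product table => independence => 0
  x <- c(0, 0, 1, 1); y <- c(0, 1, 0, 1)
  expect_equal(symmetricUncertainty(x, y), 0)
  expect_error(symmetricUncertainty(1:3, 1:4), "equal length")
  # hand-computed 2x2: x=(0,0,1,1), y=(0,1,1,1): joint (1/4,1/4,0,1/2)
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  hx <- h(c(.5, .5)); hy <- h(c(.25, .75))
  mi <- hx + hy - h(c(.25, .25, .5))
  expect_equal(symmetricUncertainty(c(0, 0, 1, 1), c(0, 1, 1, 1)),
               2 * mi / (hx + hy), tolerance = 1e-12)
})

test_that("constant attributes have zero symmetric uncertainty by convention", {
  expect_equal(symmetricUncertainty(rep(1, 6), c(1, 2, 1, 2, 1, 2)), 0)
})

test_that("CFS merit reduces to r_cf at k = 1 and is 0 at k = 0", {
  toy <- overlapToy()
  m1 <- cfsMerit("f1", toy$table, toy$labels)
  prep <- BioassayTriage:::cfsPrepare(toy$table, toy$labels)
  expect_equal(m1$merit, unname(prep$rcf["f1"]), tolerance = 1e-12)
  m0 <- cfsMerit(character(0), toy$table, toy$labels)
  expect_equal(m0$merit, 0)
  expect_error(cfsMerit("nope", toy$table, toy$labels), "unknown column")
})

test_that("duplicating a feature brings no merit gain", {
  toy <- overlapToy()
  tab <- cbind(toy$table, f1_copy = toy$table[, "f1"])
  m1 <- cfsMerit("f1", tab, toy$labels)
  m2 <- cfsMerit(c("f1", "f1_copy"), tab, toy$labels)
  # k*r_cf/sqrt(k + k(k-1)*r_ff) at k = 2, r_ff = 1 collapses back to r_cf:
  # a perfectly redundant feature cannot raise the merit
  expect_lte(m2$merit, m1$merit + 1e-12)
  expect_equal(m2$r_ff_mean, 1, tolerance = 1e-12)
  # adding an informative, non-redundant feature does raise it
  m3 <- cfsMerit(c("f1", "b1"), tab, toy$labels)
  expect_gt(m3$merit, 0)
})

test_that("best-first equals exhaustive search on a 4-feature table", {
  toy <- randomCfsTable(p = 4, n = 40, seed = 11)
  res <- bestFirstSearch(toy$table, toy$labels)
  expect_equal(res$merit, exhaustiveBestMerit(toy$table, toy$labels),
               tolerance = 1e-12)
})

test_that("pure-noise features give a subset of size <= 1", {
  withSeed(13, {
    n <- 40
    lab <- rep(c("active", "inactive"), n / 2)
    vals <- matrix(sample(0:1, n * 5, replace = TRUE), n, 5,
                   dimnames = list(NULL, paste0("n", 1:5)))
    res <- bestFirstSearch(vals, lab)
    brute <- exhaustiveBestMerit(vals, lab)
    expect_equal(res$merit, brute, tolerance = 1e-12)
    expect_lte(res$k, 1 + sum(res$merit > 1e-9) * 5)  # tiny merit => tiny set
  })
})

test_that("stale_limit = 0 performs a single expansion from the start state", {
  toy <- randomCfsTable(p = 6, n = 40, seed = 4)
  res <- bestFirstSearch(toy$table, toy$labels, stale_limit = 0)
  prep <- BioassayTriage:::cfsPrepare(toy$table, toy$labels)
  singles <- vapply(seq_len(6), function(i)
    BioassayTriage:::cfsMeritIdx(prep, i)$merit, numeric(1))
  expect_equal(res$merit, max(singles), tolerance = 1e-12)
  expect_identical(res$k, 1L)
})

test_that("forward search merit dominates every singleton", {
  toy <- randomCfsTable(p = 8, n = 50, seed = 6)
  res <- bestFirstSearch(toy$table, toy$labels)
  prep <- BioassayTriage:::cfsPrepare(toy$table, toy$labels)
  for (i in seq_len(8))
    expect_gte(res$merit + 1e-12,
               BioassayTriage:::cfsMeritIdx(prep, i)$merit)
})

test_that("search is deterministic and direction argument is honoured", {
  toy <- randomCfsTable(p = 7, n = 50, seed = 15)
  a <- bestFirstSearch(toy$table, toy$labels)
  b <- bestFirstSearch(toy$table, toy$labels)
  expect_identical(a, b)
  bw <- bestFirstSearch(toy$table, toy$labels, direction = "backward")
  bi <- bestFirstSearch(toy$table, toy$labels, direction = "bidirectional")
  expect_true(bw$merit >= 0 && bi$merit + 1e-12 >= a$merit)
})

test_that("planted informative descriptors are recovered", {
  # two strongly class-linked features among noise
  withSeed(30, {
    n <- 120
    lab <- rep(c("active", "inactive"), n / 2)
    y <- as.integer(lab == "active")
    g1 <- ifelse(stats::runif(n) < 0.05, 1L - y, y)
    g2 <- ifelse(stats::runif(n) < 0.10, 1L - y, y)
    noise <- matrix(sample(0:1, n * 6, replace = TRUE), n, 6)
    vals <- cbind(g1 = g1, g2 = g2, noise)
    colnames(vals)[3:8] <- paste0("z", 1:6)
    res <- bestFirstSearch(vals, lab)
    expect_true(all(c("g1", "g2") %in% res$subset))
  })
})

test_that("selected-descriptor lists round-trip through files", {
  path <- tempfile(fileext = ".txt")
  writeSelectedDescriptors(c("a", "b"), path)
  expect_identical(readSelectedDescriptors(path), c("a", "b"))
})
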