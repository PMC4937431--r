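test_that("logarithmic lengths match their closed forms", {
  expect_equal(logarithmicLength(4), 1)
  expect_equal(doubleLogarithmicLength(4), 2)
  expect_equal(round(doubleLogarithmicLength(1000), 2), 9.97)
  expect_equal(round(doubleLogarithmicLength(1e6), 2), 19.93)
  expect_error(logarithmicLength(1))
})

test_that("entropic decomposition conserves LG and flags boundary violations", {
  # boundary cases: e2lg at either end of the admissible interval
  c1 <- entropicComponents(2 * logarithmicLength(1024), 1024)
  expect_equal(c1$ac, 0)
  expect_equal(c1$ec, logarithmicLength(1024))
  expect_false(c1$withinBounds)
  c2 <- entropicComponents(logarithmicLength(1024), 1024)
  expect_equal(c2$ec, 0)
  expect_false(c2$withinBounds)

  c3 <- entropicComponents(8.2, 1024)
  expect_true(c3$withinBounds)
  expect_equal(c3$ec + c3$ac, logarithmicLength(1024))
})

test_that("lexical index is 1 in the random limit and large for repetitive genomes", {
  r <- generateRandomGenome(2e5, seed = 21)
  expect_lt(abs(lexicalIndex(r) - 1), 0.05)

  # poly-a: at k = 2LG ~ 20, one distinct word vs ~n occurrences
  a <- GenomeSequence(strrep("a", 2^20))
  lx <- lexicalIndex(a)
  expect_equal(lx, 2^20 - 19)  # k1 = k2 = 20, W = n - k + 1, |D| = 1

  # LX >= 1 always (distinct <= occurrences)
  set.seed(9)
  for (trial in 1:8) {
    g <- makeFixture("block-mixture", n = 3e4, seed = trial,
                     orderedFraction = runif(1, 0, 0.9))
    expect_gte(lexicalIndex(g), 1)
    expect_gte(lexicalIndex(g, method = "round"), 1)
  }
})

test_that("biobit vanishes at both ends and peaks at gamma/(2 gamma + 2 delta)", {
  expect_equal(biobit(0, lg = 10), 0)
  expect_equal(biobit(0.5, lg = 10), 0)
  expect_error(biobit(-0.1, lg = 10))
  expect_lt(biobit(0.8, lg = 10), 0)  # super-ordered: flagged as <= 0

  expect_equal(biobitArgmax(), 0.5 / 7)
  expect_equal(biobitArgmax(BBParams(gamma = 1, delta = 1)), 0.25)

  # grid search confirms the analytic maximizer for the default exponents
  afGrid <- seq(0, 0.5, by = 1e-4)
  vals <- biobit(afGrid, lg = 1)
  expect_lt(abs(afGrid[which.max(vals)] - biobitArgmax()), 2e-4)
  # and for another exponent pair
  p <- BBParams(gamma = 2, delta = 5)
  vals2 <- biobit(afGrid, lg = 1, params = p)
  expect_lt(abs(afGrid[which.max(vals2)] - biobitArgmax(p)), 2e-4)
})

test_that("the one-shot index pipeline satisfies the conservation identities", {
  for (g in list(generateRandomGenome(5e4, seed = 3),
                 makeFixture("block-mixture", n = 5e4, seed = 3,
                             orderedFraction = 0.1),
                 GenomeSequence(c("ACGTACGTACGTACGT", strrep("ac", 40))))) {
    ix <- computeIndexes(g)
    expect_equal(ix@ec + ix@ac, ix@lg, tolerance = 1e-12)
    expect_equal(ix@twoLG, 2 * ix@lg)
    expect_equal(ix@ec, ix@e2lg - ix@lg)
    expect_equal(ix@ac, ix@twoLG - ix@e2lg)
    expect_equal(ix@af, ix@ac / ix@lg)
    expect_equal(ix@eh, 1 - 2 * ix@af)
    expect_equal(ix@bb, biobit(ix@af, ix@lg, ix@params))
  }
  expect_error(computeIndexes(GenomeSequence("AC")), "too short")
})

test_that("random genomes have near-zero anti-entropy and near-unit lexical index", {
  ix <- computeIndexes(generateRandomGenome(2e5, seed = 12))
  # Proposition-3 regime: AC within the gap bound plus chance-repeat slack
  expect_lt(ix@ac, randomEntropyGapBound(2e5) + 0.001)
  expect_gt(ix@ac, 0)
  expect_lt(ix@lx, 1.01)
  expect_lt(ix@bb, 0.1 * ix@lg)
})

test_that("period-4 genomes are super-ordered: AF high, biobit collapses", {
  ix <- computeIndexes(makeFixture("periodic", n = 2^16))
  expect_gt(ix@af, 0.5)
  expect_lte(ix@bb, 0)
  expect_gt(ix@lx, 1000)
})

test_that("indexes are invariant under run permutation", {
  set.seed(17)
  runs <- randomRunsText(4, 4000)
  g1 <- GenomeSequence(paste(runs, collapse = "N"))
  g2 <- GenomeSequence(paste(rev(runs), collapse = "N"))
  ix1 <- computeIndexes(g1); ix2 <- computeIndexes(g2)
  expect_equal(ix1@e2lg, ix2@e2lg)
  expect_equal(ix1@ac, ix2@ac)
  expect_equal(ix1@lx, ix2@lx)
  expect_equal(ix1@bb, ix2@bb)
})

test_that("the integer-k lexical bound lg2(LX) <= AC_k holds on all genomes", {
  set.seed(23)
  cases <- c(list(generateRandomGenome(3e4, seed = 1),
                  makeFixture("periodic", n = 3e4),
                  GenomeSequence(strrep("a", 3e4))),
             lapply(c(0.05, 0.3, 0.7), function(f)
               makeFixture("block-mixture", n = 3e4, seed = 5,
                           orderedFraction = f)))
  for (g in cases) {
    ix <- computeIndexes(g)
    expect_lte(log2(ix@lxRound), log2(ix@n) - ix@ekRound + 1e-9)
  }
})

test_that("index serialization keeps full precision in JSON and 4 decimals in TSV", {
  ix <- computeIndexes(generateRandomGenome(2e4, seed = 6))
  js <- jsonlite::fromJSON(indexesJSON(ix))
  expect_equal(js$AC, ix@ac)
  expect_equal(js$BB, ix@bb)
  expect_equal(js$bb_params$delta, 3)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeIndexesTSV(ix, tsv)
  df <- read.delim(tsv, colClasses = "character")
  expect_equal(names(df), c("LG", "EC", "AC", "LX", "AF", "EH", "BB"))
  expect_equal(df$LG, formatC(ix@lg, format = "f", digits = 4))
})
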