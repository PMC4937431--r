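test_that("empirical entropy matches hand computations and the naive oracle", {
  expect_equal(empiricalEntropy(kmerSpectrum(GenomeSequence("AAAA"), 1L)), 0)
  expect_equal(empiricalEntropy(kmerSpectrum(GenomeSequence("ACGT"), 1L)), 2)
  expect_equal(empiricalEntropy(kmerSpectrum(GenomeSequence("ACGTACGT"), 2L)),
               (6 / 7) * log2(7 / 2) + (1 / 7) * log2(7))

  set.seed(31)
  for (trial in 1:20) {
    g <- GenomeSequence(paste(randomRunsText(1, 300), collapse = ""))
    for (k in c(1L, 3L, 5L)) {
      expect_equal(empiricalEntropy(kmerSpectrum(g, k)),
                   oracleEntropy(genomeRuns(g), k))
    }
  }
})

test_that("entropy respects the equipartition bound with equality at all-hapax k", {
  set.seed(13)
  g <- generateRandomGenome(5000, seed = 8)
  st <- buildSuffixStructure(g)
  m <- mrl(st)
  for (k in c(1L, 3L, 8L, m, m + 1L, m + 3L)) {
    sp <- kmerSpectrum(st, k)
    ek <- empiricalEntropy(sp)
    expect_lte(ek, log2(occurrenceTotal(sp)) + 1e-12)
    if (k > m)  # beyond mrl all words are hapaxes: uniform distribution
      expect_equal(ek, log2(occurrenceTotal(sp)))
  }
})

test_that("entropy profile rises with k on random genomes and interpolates E_2LG", {
  g <- generateRandomGenome(4096, seed = 4)   # 2LG = 12 exactly
  prof <- entropyProfile(g, 1L, 12L)
  expect_true(all(diff(prof@ek) > 0))  # strictly rising up to k = 2LG
  expect_equal(prof@k1, 12L)
  expect_equal(prof@k2, 12L)
  expect_equal(prof@e2lg, prof@ek[prof@k == 12L])  # integer case: E_12 as is
  expect_equal(interpolatedE2LG(prof), prof@e2lg)

  g2 <- generateRandomGenome(3000, seed = 4)  # 2LG ~ 11.55
  prof2 <- entropyProfile(g2, 10L, 13L)
  expect_equal(c(prof2@k1, prof2@k2), c(11L, 12L))
  w <- log2(3000) - 11
  e11 <- prof2@ek[prof2@k == 11L]; e12 <- prof2@ek[prof2@k == 12L]
  expect_equal(prof2@e2lg, e11 + w * (e12 - e11))
  expect_true(prof2@e2lg >= min(e11, e12) && prof2@e2lg <= max(e11, e12))

  # range that misses the bracketing word lengths flags e2lg as absent
  expect_message(p3 <- entropyProfile(g2, 1L, 3L), "does not bracket")
  expect_true(is.na(p3@e2lg))
  expect_error(interpolatedE2LG(p3))
  expect_error(entropyProfile(g2, 5L, 3L), "kMin")

  prof4 <- entropyProfile(GenomeSequence("ACGTACGT"), 2L, 2L)
  expect_equal(prof4@ek, (6 / 7) * log2(7 / 2) + (1 / 7) * log2(7))
})

test_that("closed-form entropy bounds behave as derived", {
  expect_equal(maxEntropyBound(1000, 10), log2(991))
  expect_equal(maxEntropyBound(4, 1), 2)
  expect_equal(maxEntropyBound(1000), log2(1000))
  expect_error(maxEntropyBound(10, 10), "smaller than n")

  expect_equal(randomEntropyGapBound(1024), log2(1024 / 1015))
  expect_equal(randomEntropyGapBound(1e6), log2(1e6 / (1e6 - 20 + 1)))
  expect_lt(randomEntropyGapBound(1e6), 3e-5)
  # bound at word length k never exceeds the global bound
  for (n in c(100, 5000, 1e6))
    for (k in c(1, 10, 50))
      expect_lte(maxEntropyBound(n, k), log2(n))
  # gap bound strictly decreasing in n while ceiling(lg2 n) stays constant,
  # and jumping up each time the bracketing word length increments
  ns <- 16:600
  b <- vapply(ns, randomEntropyGapBound, numeric(1))
  sameK <- diff(ceiling(log2(ns))) == 0
  expect_true(all(diff(b)[sameK] < 0))
  expect_true(all(diff(b)[!sameK] > 0))
})

test_that("random genomes sit at the entropy gap bound up to the chance-repeat deficit", {
  # at k = ceiling(lg2 n): the gap lg2(n) - E_k is never below the bound
  # (equipartition theorem) and exceeds it only by the deficit that chance
  # repeats cause, here bounded by a generous 40/W bits
  for (n in c(1e4, 1e5)) {
    k <- as.integer(ceiling(log2(n)))
    bound <- randomEntropyGapBound(n)
    for (s in 1:10) {
      sp <- kmerSpectrum(generateRandomGenome(n, seed = 1000 + s), k)
      gap <- log2(n) - empiricalEntropy(sp)
      expect_gte(gap, bound - 1e-9)
      expect_lte(gap, bound + 40 / occurrenceTotal(sp))
    }
  }
})

test_that("profile exports round-trip through TSV and JSON", {
  g <- generateRandomGenome(2000, seed = 2)
  prof <- entropyProfile(g, 9L, 12L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeProfileTSV(prof, tsv)
  df <- read.delim(tsv)
  expect_equal(df$k, 9:12)
  expect_equal(df$entropy_bits, prof@ek)
  js <- jsonlite::fromJSON(profileJSON(prof))
  expect_equal(js$e2lg, prof@e2lg)
  expect_equal(js$k1, 10)
  expect_equal(unname(unlist(js$points)), prof@ek)
})
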