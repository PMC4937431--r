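# Independent brute-force oracles, deliberately naive: substring
# enumeration and table(), no suffix arrays.

oracleWords <- function(runs, k) {
  unlist(lapply(runs, function(r) {
    nr <- nchar(r)
    if (nr < k) return(character())
    substring(r, 1:(nr - k + 1), k:nr)
  }))
}

oracleSpectrum <- function(runs, k) {
  words <- oracleWords(runs, k)
  tb <- table(words)
  hist <- table(as.integer(tb))
  list(distinct = length(tb), occurrences = sum(tb),
       multiplicity = as.numeric(names(hist)),
       count = as.numeric(hist),
       hapax = sum(tb == 1), repeats = sum(tb > 1))
}

oracleEntropy <- function(runs, k) {
  words <- oracleWords(runs, k)
  f <- as.numeric(table(words)) / length(words)
  -sum(f * log2(f))
}

# longest repeated substring length; binary search is valid because
# "some word of length L repeats" is monotone in L
oracleMrl <- function(runs) {
  hasRepeat <- function(L) {
    if (L == 0) return(TRUE)
    anyDuplicated(oracleWords(runs, L)) > 0
  }
  lo <- 0L
  hi <- max(nchar(runs))
  while (lo < hi) {
    mid <- as.integer(ceiling((lo + hi) / 2))
    if (hasRepeat(mid)) lo <- mid else hi <- mid - 1L
  }
  lo
}

# random multi-run genome text for property tests
randomRunsText <- function(nRuns, maxLen) {
  vapply(seq_len(nRuns), function(i) {
    paste(sample(c("a", "c", "g", "t"), sample.int(maxLen, 1),
                 replace = TRUE), collapse = "")
  }, character(1))
}

expectSpectrumMatchesOracle <- function(genome, k) {
  sp <- kmerSpectrum(genome, k)
  or <- oracleSpectrum(genomeRuns(genome), k)
  expect_equal(distinctWords(sp), or$distinct)
  expect_equal(occurrenceTotal(sp), or$occurrences)
  expect_equal(sp@multiplicity, or$multiplicity)
  expect_equal(sp@count, or$count)
  expect_equal(hapaxCount(sp), or$hapax)
  expect_equal(repeatCount(sp), or$repeats)
  invisible(sp)
}
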