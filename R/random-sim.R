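#' Generate a seeded Bernoullian (random) genome
#'
#' Produces a single-run genome whose symbols are drawn iid uniformly from
#' {a, c, g, t} — the blind-urn model of a random genome.  The same
#' (n, seed) pair always yields the identical sequence; the caller's RNG
#' state is left untouched.
#'
#' @param n genome length, >= 1.
#' @param seed integer seed; NULL uses (and advances) the current RNG state.
#' @return a [GenomeSequence-class] with one run of length n.
#' @examples
#' g <- generateRandomGenome(1000, seed = 7)
#' identical(genomeRuns(g), genomeRuns(generateRandomGenome(1000, seed = 7)))
#' @export
generateRandomGenome <- function(n, seed = NULL) {
  n <- .assertScalarCount(n, "n")
  codes <- .randomCodes(n, seed)
  label <- if (is.null(seed)) sprintf("random_n%d", n)
           else sprintf("random_n%d_seed%d", n, as.integer(seed))
  new("GenomeSequence", runs = .codesToString(codes), n = n,
      sourceLabel = label)
}

#' Expected all-hapax word length of a random genome
#'
#' The smallest integer k with 2^k >= n - k + 1: the balance point at which
#' the expected occurrence probability of a k-mer, (n - k + 1)/4^k, equals
#' the probability 1/(n - k + 1) of occurring exactly once.  It estimates
#' mrl(R) + 1 for random genomes of length n and is approximately
#' ceiling(lg2 n).
#'
#' @param n genome length, >= 16.
#' @return integer(1).
#' @examples
#' expectedHapaxLength(1000)  # 10: 2^10 = 1024 >= 991
#' expectedHapaxLength(1024)  # 10
#' @export
expectedHapaxLength <- function(n) {
  n <- .assertScalarCount(n, "n", min = 16)
  k <- 1L
  while (2^k < n - k + 1) k <- k + 1L
  k
}

#' Maximal-repeat-length statistics over random-genome trials
#'
#' For each length, generates \code{trials} independent seeded Bernoullian
#' genomes, computes the maximal repeat length of each via the suffix-array
#' engine, and aggregates min, max, sample standard deviation and mean of
#' mrl + 1 alongside lg2(length).  The master seed deterministically spawns
#' one sub-seed per trial (drawn up front from a seeded stream), so results
#' are reproducible and independent of evaluation order.  With a good
#' approximation avg(mrl + 1) is slightly above lg2(length).
#'
#' @param lengths vector of genome lengths, each >= 2.
#' @param trials number of repetitions per length (>= 2, default 100).
#' @param seed master seed.
#' @param maxLength resource guard; lengths above it are rejected.
#' @return data.frame with columns length, min, max, sd, avg, lg2 (one row
#'   per length).
#' @examples
#' mrlTrials(1000, trials = 10, seed = 1)
#' @export
mrlTrials <- function(lengths, trials = 100L, seed = 1L, maxLength = 2e8) {
  trials <- .assertScalarCount(trials, "trials", min = 2)
  if (!length(lengths) || any(!is.finite(lengths)) || any(lengths < 2))
    stop("lengths must be positive (>= 2)")
  if (any(lengths > maxLength))
    stop("length above the resource guard maxLength = ", format(maxLength))
  lengths <- as.integer(lengths)
  subseeds <- withSeed(seed,
    matrix(sample.int(2147483646L, length(lengths) * trials),
           nrow = length(lengths)))
  rows <- lapply(seq_along(lengths), function(i) {
    n <- lengths[i]
    vals <- vapply(seq_len(trials), function(j) {
      .cppMrlCodes(.randomCodes(n, subseeds[i, j])) + 1L
    }, integer(1))
    data.frame(length = n, min = min(vals), max = max(vals),
               sd = stats::sd(vals), avg = mean(vals), lg2 = log2(n))
  })
  do.call(rbind, rows)
}
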