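#' Deterministic synthetic genome fixtures
#'
#' Generates the ideal-genome test corpus: fully random (Bernoullian)
#' genomes, fully periodic genomes, block mixtures with a tunable ordered
#' fraction, and literal hand-checkable strings.  A block mixture
#' concatenates a periodic block of length \code{round(orderedFraction * n)}
#' with a random block covering the remainder, as a single run; sweeping the
#' fraction from 0 to 1 moves the anti-entropic fraction AF from ~0 to near
#' its maximum for that length, which is how the rise-and-fall shape of the
#' biobit can be observed empirically.  The ordered fraction is a modelling
#' dial of this generator and does not correspond to a measured genomic
#' quantity.
#'
#' @param kind one of "random", "periodic", "block-mixture", "literal".
#' @param n effective length of the generated genome (ignored for
#'   "literal").
#' @param seed integer seed for the random parts.
#' @param period period string for periodic/mixture kinds (default "acgt").
#' @param orderedFraction fraction in \code{[0, 1]} of the genome covered by
#'   the periodic block ("block-mixture" only).
#' @param literal raw sequence text for kind "literal" (normalized as in
#'   [GenomeSequence()]).
#' @return a [GenomeSequence-class]; deterministic for a given spec and
#'   seed.
#' @examples
#' makeFixture("periodic", n = 64)                  # mrl = 60
#' makeFixture("block-mixture", n = 4096, seed = 1, orderedFraction = 0.1)
#' @export
makeFixture <- function(kind = c("random", "periodic", "block-mixture",
                                 "literal"),
                        n = NULL, seed = 1L, period = "acgt",
                        orderedFraction = 0.5, literal = "") {
  kind <- match.arg(kind)
  if (kind == "literal") {
    g <- GenomeSequence(literal, sourceLabel = "fixture_literal")
    return(g)
  }
  n <- .assertScalarCount(n, "n")
  period <- tolower(period)
  if (kind != "random" && (nchar(period) == 0 || grepl("[^acgt]", period)))
    stop("period must be a non-empty string over a, c, g, t")
  if (kind == "random") {
    g <- generateRandomGenome(n, seed = seed)
    g@sourceLabel <- sprintf("fixture_random_n%d_seed%d", n,
                             as.integer(seed))
    return(g)
  }
  periodicBlock <- function(len) {
    if (len == 0) return("")
    substr(strrep(period, ceiling(len / nchar(period))), 1L, len)
  }
  if (kind == "periodic") {
    run <- periodicBlock(n)
    return(new("GenomeSequence", runs = run, n = n,
               sourceLabel = sprintf("fixture_periodic_%s_n%d", period, n)))
  }
  # block-mixture
  if (length(orderedFraction) != 1L || !is.finite(orderedFraction) ||
      orderedFraction < 0 || orderedFraction > 1)
    stop("orderedFraction must lie in [0, 1]")
  nOrd <- as.integer(round(orderedFraction * n))
  nRnd <- n - nOrd
  rnd <- if (nRnd > 0) .codesToString(.randomCodes(nRnd, seed)) else ""
  run <- paste0(periodicBlock(nOrd), rnd)
  new("GenomeSequence", runs = run, n = n,
      sourceLabel = sprintf("fixture_mixture_f%.3f_n%d_seed%d",
                            orderedFraction, n, as.integer(seed)))
}
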