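#' Empirical k-entropy of a k-mer spectrum
#'
#' The Shannon entropy of the empirical k-mer frequency distribution,
#' \deqn{E_k = -\sum_{\alpha \in D_k} f(\alpha)\, \lg_2 f(\alpha),}
#' with \eqn{f(\alpha) = mult(\alpha) / W_k} and \eqn{W_k} the occurrence
#' total.  Only words occurring in the genome contribute (no zero-probability
#' terms); the sum is taken over the multiplicity histogram, so words of equal
#' multiplicity share one term.  By the equipartition property
#' \eqn{E_k \le \lg_2 W_k}, with equality exactly when all k-mers are hapaxes.
#'
#' @param spectrum a [KmerSpectrum-class] with at least one occurrence.
#' @return numeric(1), entropy in bits.
#' @examples
#' empiricalEntropy(kmerSpectrum(GenomeSequence("AAAA"), 1L))      # 0 bits
#' empiricalEntropy(kmerSpectrum(GenomeSequence("ACGT"), 1L))      # 2 bits
#' empiricalEntropy(kmerSpectrum(GenomeSequence("ACGTACGT"), 2L))  # ~1.9502
#' @rdname empiricalEntropy
#' @export
setMethod("empiricalEntropy", "KmerSpectrum", function(spectrum) {
  w <- spectrum@occurrences
  if (!length(w) || w < 1)
    stop("spectrum has no occurrences")
  sum(spectrum@count * (spectrum@multiplicity / w) *
        log2(w / spectrum@multiplicity))
})

#' Logarithmic and double logarithmic genome length
#'
#' \code{logarithmicLength} returns LG = lg4(n) = lg2(n)/2;
#' \code{doubleLogarithmicLength} returns 2LG = lg2(n), the word length at
#' which random genomes attain maximal entropy (for the human genome 2LG lies
#' between 31 and 32).
#'
#' @param n effective genome length, n >= 2.
#' @return numeric(1), dimensionless.
#' @examples
#' logarithmicLength(4)            # 1
#' doubleLogarithmicLength(1000)   # 9.97
#' @export
logarithmicLength <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 2)
    stop("n must be a single length >= 2")
  log2(n) / 2
}

#' @rdname logarithmicLength
#' @export
doubleLogarithmicLength <- function(n) 2 * logarithmicLength(n)

# bracketing integers for the interpolation at 2LG
.bracket2LG <- function(n) {
  twoLG <- doubleLogarithmicLength(n)
  if (twoLG == floor(twoLG)) {
    list(k1 = as.integer(twoLG), k2 = as.integer(twoLG), twoLG = twoLG,
         w = 0)
  } else {
    k1 <- as.integer(floor(twoLG))
    list(k1 = k1, k2 = k1 + 1L, twoLG = twoLG, w = twoLG - k1)
  }
}

# linear interpolation used for both entropies and lexical ratios
.interp2LG <- function(v1, v2, n) {
  br <- .bracket2LG(n)
  if (br$k1 == br$k2) v1 else v1 + br$w * (v2 - v1)
}

#' Entropy interpolated at the double logarithmic length
#'
#' When 2LG = lg2(n) is not an integer, E_2LG is the linear interpolation
#' between E_k1 and E_k2, where k1 < 2LG < k2 are the bracketing integers:
#' E_2LG = E_k1 + (2LG - k1) (E_k2 - E_k1).  When lg2(n) is an integer,
#' E_2LG = E_k1 exactly.
#'
#' @param profile an [EntropyProfile-class] whose range covers k1 and k2.
#' @param n effective length; defaults to the profile's own n.
#' @return numeric(1), bits.
#' @examples
#' p <- entropyProfile(GenomeSequence(strrep("ACGT", 8)), 1L, 8L)
#' interpolatedE2LG(p)
#' @rdname interpolatedE2LG
#' @export
setMethod("interpolatedE2LG", "EntropyProfile", function(profile, n = NULL) {
  if (is.null(n)) n <- profile@n
  br <- .bracket2LG(n)
  i1 <- match(br$k1, profile@k)
  i2 <- match(br$k2, profile@k)
  if (is.na(i1) || is.na(i2))
    stop("profile does not contain the bracketing entropies E_", br$k1,
         " and E_", br$k2)
  .interp2LG(profile@ek[i1], profile@ek[i2], n)
})

#' Entropy profile over a range of word lengths
#'
#' Computes E_k for every k in \code{[kMin, kMax]} from a single suffix
#' structure, and the interpolated E_2LG when the bracketing word lengths
#' fall inside the range (otherwise \code{e2lg} is NA and a message is
#' emitted).
#'
#' @param genome a [GenomeSequence-class].
#' @param kMin,kMax word length range, \code{1 <= kMin <= kMax <=} maximum
#'   run length.
#' @return an [EntropyProfile-class].
#' @examples
#' entropyProfile(GenomeSequence("ACGTACGT"), 2L, 2L)  # E_2 ~ 1.9502
#' @rdname entropyProfile
#' @export
setMethod("entropyProfile", "GenomeSequence",
          function(genome, kMin = 1L, kMax) {
  kMin <- .assertScalarCount(kMin, "kMin")
  kMax <- .assertScalarCount(kMax, "kMax")
  if (kMin > kMax)
    stop("kMin must not exceed kMax")
  if (kMax > max(nchar(genome@runs)))
    stop("kMax exceeds the maximum run length")
  st <- buildSuffixStructure(genome)
  ks <- seq.int(kMin, kMax)
  ek <- vapply(ks, function(k)
    empiricalEntropy(.spectrumFromStructure(st, k)), numeric(1))
  br <- .bracket2LG(genome@n)
  e2lg <- NA_real_
  if (br$k1 >= kMin && br$k2 <= kMax) {
    e2lg <- .interp2LG(ek[br$k1 - kMin + 1L], ek[br$k2 - kMin + 1L],
                       genome@n)
  } else {
    message("profile range [", kMin, ", ", kMax, "] does not bracket 2LG = ",
            format(br$twoLG, digits = 6), "; e2lg not computed")
  }
  new("EntropyProfile", genomeLabel = genome@sourceLabel, n = genome@n,
      k = as.integer(ks), ek = ek, e2lg = e2lg,
      k1 = br$k1, k2 = br$k2)
})

#' Maximal entropy bound for genomes of length n
#'
#' For word length k, the empirical k-entropy over genomes of length n is at
#' most lg2(n - k + 1), attained when all k-mers are hapaxes (equipartition);
#' lg2(n) bounds it globally.  With \code{k = NULL} the global bound lg2(n)
#' is returned.
#'
#' @param n genome length; @param k word length with \code{1 <= k < n}, or
#'   NULL for the global bound.
#' @return numeric(1), bits.
#' @examples
#' maxEntropyBound(1000, 10)   # lg2(991) ~ 9.9869
#' maxEntropyBound(1000)       # lg2(1000)
#' @export
maxEntropyBound <- function(n, k = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 2)
    stop("n must be a single length >= 2")
  if (is.null(k)) return(log2(n))
  k <- .assertScalarCount(k, "k")
  if (k >= n) stop("k must be smaller than n")
  log2(n - k + 1)
}

#' Entropy gap bound for random genomes
#'
#' The guaranteed distance between the global entropy bound lg2(n) and the
#' maximal entropy attainable at the critical word length k = ceiling(lg2 n):
#' lg2( n / (n - ceiling(lg2 n) + 1) ).  For a maximal-entropy (all-hapax)
#' genome at that k the gap equals this bound exactly; real random genomes
#' exceed it only by the tiny entropy deficit caused by chance repeats.
#' The bound tends to 0 as n grows.
#'
#' @param n genome length with \code{n > ceiling(lg2 n)}.
#' @return numeric(1), bits.
#' @examples
#' randomEntropyGapBound(1024)  # ~0.0127
#' randomEntropyGapBound(1e6)   # ~2.9e-5
#' @export
randomEntropyGapBound <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 2)
    stop("n must be a single length >= 2")
  kc <- ceiling(log2(n))
  if (n <= kc) stop("n must exceed ceiling(lg2(n))")
  log2(n / (n - kc + 1))
}

setMethod("show", "EntropyProfile", function(object) {
  cat(sprintf("EntropyProfile '%s' (n = %s): k in [%d, %d]\n",
              object@genomeLabel, format(object@n, big.mark = ","),
              min(object@k), max(object@k)))
  cat(sprintf("  E_2LG = %s (k1 = %d, k2 = %d)\n",
              ifelse(is.na(object@e2lg), "not computed",
                     format(object@e2lg, digits = 6)),
              object@k1, object@k2))
})

#' Export an entropy profile
#'
#' \code{writeProfileTSV} writes a per-k table (k, entropy_bits);
#' \code{profileJSON} returns the profile as a JSON string with fields n,
#' e2lg, k1, k2 and points.
#'
#' @param profile an [EntropyProfile-class].
#' @param path output path.
#' @return the path (TSV), or a JSON string.
#' @export
writeProfileTSV <- function(profile, path) {
  utils::write.table(data.frame(k = profile@k, entropy_bits = profile@ek),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeProfileTSV
#' @export
profileJSON <- function(profile) {
  jsonlite::toJSON(list(
    genome = profile@genomeLabel, n = profile@n,
    e2lg = profile@e2lg, k1 = profile@k1, k2 = profile@k2,
    points = stats::setNames(as.list(profile@ek), profile@k)),
    auto_unbox = TRUE, digits = NA, null = "null", na = "null")
}
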