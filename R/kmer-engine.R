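#' Build the suffix structure of a genome
#'
#' Constructs the suffix array (SA-IS) and capped LCP array (Kasai) over the
#' separator-joined runs of the genome.  Substrings crossing run boundaries
#' are not representable in the index, so k-mer groups and repeated words are
#' confined to unambiguous sequence.  Building once and querying repeatedly
#' is much cheaper than rebuilding per k.
#'
#' @param genome a [GenomeSequence-class].
#' @return a [SuffixStructure-class].
#' @examples
#' st <- buildSuffixStructure(GenomeSequence("ACGTACGT"))
#' mrl(st)                 # 4: "acgt" occurs twice
#' kmerSpectrum(st, 2L)
#' @rdname buildSuffixStructure
#' @export
setMethod("buildSuffixStructure", "GenomeSequence", function(genome) {
  validObject(genome)
  res <- .cppBuildSuffix(genome@runs)
  new("SuffixStructure", sa = res$sa, lcp = res$lcp, valid = res$valid,
      n = genome@n, textLength = as.integer(res$textLength))
})

.spectrumFromStructure <- function(structure, k) {
  k <- .assertScalarCount(k, "k")
  res <- .cppSpectrum(structure@sa, structure@lcp, structure@valid, k)
  if (res$distinct == 0)
    stop("k = ", k, " exceeds every run length: empty spectrum")
  hap <- sum(res$count[res$multiplicity == 1])
  new("KmerSpectrum", k = k, distinct = res$distinct,
      occurrences = res$occurrences, multiplicity = res$multiplicity,
      count = res$count, hapaxCount = hap,
      repeatCount = res$distinct - hap)
}

#' k-mer spectrum of a genome
#'
#' Computes the dictionary size |D_k|, the occurrence total W_k and the
#' multiplicity histogram of the k-mers of a genome (overlapping occurrences
#' counted, never spanning run boundaries).  For a multi-run genome,
#' W_k = sum over runs of max(0, run length - k + 1).  Only observed words
#' are represented, so large k (the working range for genome indexes runs up
#' to ~36) poses no problem.
#'
#' @param x a [GenomeSequence-class] or a prebuilt [SuffixStructure-class].
#' @param k word length, \code{1 <= k <=} maximum run length.
#' @return a [KmerSpectrum-class].
#' @examples
#' kmerSpectrum(GenomeSequence("ACGTACGT"), 2L)  # 4 distinct, 7 occurrences
#' @rdname kmerSpectrum
#' @export
setMethod("kmerSpectrum", "GenomeSequence", function(x, k) {
  .spectrumFromStructure(buildSuffixStructure(x), k)
})

#' @rdname kmerSpectrum
#' @export
setMethod("kmerSpectrum", "SuffixStructure", function(x, k) {
  .spectrumFromStructure(x, k)
})

#' Maximal repeat length
#'
#' The length of the longest word occurring at least twice in the genome
#' (overlapping occurrences count; words never span run boundaries).  By
#' construction, every k-mer with k > mrl is a hapax, and at k = mrl at
#' least one repeat exists.  Returns 0 for a repeat-free genome.
#'
#' @param x a [GenomeSequence-class] or [SuffixStructure-class].
#' @return integer(1), the maximal repeat length.
#' @examples
#' mrl(GenomeSequence("ACGTACGT"))  # 4
#' mrl(GenomeSequence("AAAA"))      # 3 ("aaa" twice, overlapping)
#' mrl(GenomeSequence("ACGT"))      # 0
#' @rdname mrl
#' @export
setMethod("mrl", "GenomeSequence", function(x) {
  validObject(x)
  if (length(x@runs) == 1L) {
    codes <- match(strsplit(x@runs, "")[[1L]], c("a", "c", "g", "t"))
    .cppMrlCodes(codes)
  } else {
    mrl(buildSuffixStructure(x))
  }
})

#' @rdname mrl
#' @export
setMethod("mrl", "SuffixStructure", function(x) .cppMaxLcp(x@lcp))

#' @rdname accessors
setMethod("distinctWords", "KmerSpectrum", function(x) x@distinct)

#' @rdname accessors
setMethod("occurrenceTotal", "KmerSpectrum", function(x) x@occurrences)

#' @rdname accessors
setMethod("hapaxCount", "KmerSpectrum", function(x) x@hapaxCount)

#' @rdname accessors
setMethod("repeatCount", "KmerSpectrum", function(x) x@repeatCount)

#' @rdname accessors
setMethod("multiplicityHistogram", "KmerSpectrum", function(x) {
  data.frame(multiplicity = x@multiplicity, words = x@count)
})

setMethod("show", "KmerSpectrum", function(object) {
  cat(sprintf(paste0("KmerSpectrum k = %d: %s distinct / %s occurrences ",
                     "(%s hapax, %s repeat)\n"),
              object@k, format(object@distinct, big.mark = ","),
              format(object@occurrences, big.mark = ","),
              format(object@hapaxCount, big.mark = ","),
              format(object@repeatCount, big.mark = ",")))
})

setMethod("show", "SuffixStructure", function(object) {
  cat(sprintf("SuffixStructure over %s nucleotides (text length %s)\n",
              format(object@n, big.mark = ","),
              format(object@textLength, big.mark = ",")))
})

#' Export a k-mer spectrum as TSV
#'
#' \code{writeSpectrumTSV} writes a one-row summary (k, distinct,
#' occurrences, hapax_count, repeat_count); \code{writeHistogramTSV} writes
#' the multiplicity histogram (multiplicity, words).
#'
#' @param spectrum a [KmerSpectrum-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeSpectrumTSV <- function(spectrum, path) {
  df <- data.frame(k = spectrum@k, distinct = spectrum@distinct,
                   occurrences = spectrum@occurrences,
                   hapax_count = spectrum@hapaxCount,
                   repeat_count = spectrum@repeatCount)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpectrumTSV
#' @export
writeHistogramTSV <- function(spectrum, path) {
  utils::write.table(multiplicityHistogram(spectrum), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
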