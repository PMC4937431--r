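#' @rdname buildSuffixStructure
#' @export
setGeneric("buildSuffixStructure",
           function(genome) standardGeneric("buildSuffixStructure"))

#' @rdname kmerSpectrum
#' @export
setGeneric("kmerSpectrum", function(x, k) standardGeneric("kmerSpectrum"))

#' @rdname mrl
#' @export
setGeneric("mrl", function(x) standardGeneric("mrl"))

#' @rdname empiricalEntropy
#' @export
setGeneric("empiricalEntropy",
           function(spectrum) standardGeneric("empiricalEntropy"))

#' @rdname entropyProfile
#' @export
setGeneric("entropyProfile",
           function(genome, kMin = 1L, kMax) standardGeneric("entropyProfile"))

#' @rdname interpolatedE2LG
#' @export
setGeneric("interpolatedE2LG",
           function(profile, n = NULL) standardGeneric("interpolatedE2LG"))

#' @rdname lexicalIndex
#' @export
setGeneric("lexicalIndex",
           function(x, method = c("interpolate", "round"))
             standardGeneric("lexicalIndex"))

#' @rdname computeIndexes
#' @export
setGeneric("computeIndexes",
           function(genome, params = BBParams(),
                    lxMethod = c("interpolate", "round"))
             standardGeneric("computeIndexes"))

#' @rdname verifyLaws
#' @export
setGeneric("verifyLaws",
           function(ix, extraLaws = list()) standardGeneric("verifyLaws"))

#' @rdname applyEdits
#' @export
setGeneric("applyEdits",
           function(genome, plan) standardGeneric("applyEdits"))

#' Accessors for biobits objects
#'
#' \code{effectiveLength} returns the number of unambiguous nucleotides n;
#' \code{genomeRuns} the unambiguous runs; \code{sourceLabel} the genome
#' identifier; \code{distinctWords}, \code{occurrenceTotal},
#' \code{hapaxCount}, \code{repeatCount} the dictionary counts of a
#' [KmerSpectrum-class]; \code{multiplicityHistogram} its histogram as a
#' two-column data.frame.
#'
#' @param x a [GenomeSequence-class] or [KmerSpectrum-class] object.
#' @return a length-one numeric/character, or a data.frame for
#'   \code{multiplicityHistogram}.
#' @examples
#' g <- GenomeSequence("ACGTACGT")
#' effectiveLength(g)
#' sp <- kmerSpectrum(g, 2L)
#' distinctWords(sp); occurrenceTotal(sp); multiplicityHistogram(sp)
#' @name accessors
#' @export
setGeneric("effectiveLength", function(x) standardGeneric("effectiveLength"))

#' @rdname accessors
#' @export
setGeneric("genomeRuns", function(x) standardGeneric("genomeRuns"))

#' @rdname accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))

#' @rdname accessors
#' @export
setGeneric("distinctWords", function(x) standardGeneric("distinctWords"))

#' @rdname accessors
#' @export
setGeneric("occurrenceTotal", function(x) standardGeneric("occurrenceTotal"))

#' @rdname accessors
#' @export
setGeneric("hapaxCount", function(x) standardGeneric("hapaxCount"))

#' @rdname accessors
#' @export
setGeneric("repeatCount", function(x) standardGeneric("repeatCount"))

#' @rdname accessors
#' @export
setGeneric("multiplicityHistogram",
           function(x) standardGeneric("multiplicityHistogram"))
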