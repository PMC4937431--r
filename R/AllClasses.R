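#' @import methods
NULL

#' GenomeSequence: a genome as maximal unambiguous runs
#'
#' A genome is modelled as an ordered set of maximal runs over the lowercase
#' alphabet \code{{a, c, g, t}}.  Ambiguity symbols (N, IUPAC codes, gaps) and
#' record boundaries terminate runs, so that no k-mer ever spans them, and do
#' not contribute to the effective length \code{n}.
#'
#' @slot runs character vector of non-empty lowercase acgt strings, in input
#'   order.
#' @slot n numeric(1), effective length: total number of a/c/g/t symbols.
#' @slot sourceLabel character(1), free-text identifier of the genome.
#'
#' @seealso [GenomeSequence()], [readGenome()], [writeGenome()]
#' @exportClass GenomeSequence
setClass("GenomeSequence",
  representation(runs = "character", n = "numeric", sourceLabel = "character"),
  prototype(runs = character(), n = 0, sourceLabel = ""))

setValidity("GenomeSequence", function(object) {
  msgs <- character()
  if (length(object@runs) == 0L)
    msgs <- c(msgs, "genome must contain at least one run")
  if (any(nchar(object@runs) == 0L))
    msgs <- c(msgs, "runs must be non-empty strings")
  if (length(object@runs) && any(grepl("[^acgt]", object@runs)))
    msgs <- c(msgs, "runs may contain only lowercase a, c, g, t")
  if (length(object@n) != 1L || object@n != sum(nchar(object@runs)))
    msgs <- c(msgs, "n must equal the total run length")
  if (length(msgs)) msgs else TRUE
})

#' KmerSpectrum: multiplicity structure of the k-mer dictionary
#'
#' For a word length \code{k}, holds the size of the dictionary D_k (distinct
#' k-mers), the occurrence total W_k (number of k-mer positions; for a
#' single-run genome W_k = n - k + 1), and the multiplicity histogram: how many
#' distinct words occur exactly m times, for each observed multiplicity m.
#' Words with multiplicity 1 are hapaxes, words with multiplicity > 1 repeats.
#'
#' @slot k integer(1) word length.
#' @slot distinct numeric(1), |D_k|.
#' @slot occurrences numeric(1), W_k.
#' @slot multiplicity numeric vector of observed multiplicity values (sorted).
#' @slot count numeric vector, number of distinct words per multiplicity.
#' @slot hapaxCount numeric(1), words with multiplicity 1.
#' @slot repeatCount numeric(1), words with multiplicity > 1.
#'
#' @seealso [kmerSpectrum()], [empiricalEntropy()]
#' @exportClass KmerSpectrum
setClass("KmerSpectrum",
  representation(k = "integer", distinct = "numeric", occurrences = "numeric",
                 multiplicity = "numeric", count = "numeric",
                 hapaxCount = "numeric", repeatCount = "numeric"))

setValidity("KmerSpectrum", function(object) {
  msgs <- character()
  if (length(object@multiplicity) != length(object@count))
    msgs <- c(msgs, "multiplicity and count must have equal length")
  if (abs(sum(object@multiplicity * object@count) - object@occurrences) > 1e-6)
    msgs <- c(msgs, "histogram mass must equal the occurrence total")
  if (abs(object@hapaxCount + object@repeatCount - object@distinct) > 1e-6)
    msgs <- c(msgs, "hapaxCount + repeatCount must equal distinct")
  if (object@distinct > object@occurrences)
    msgs <- c(msgs, "distinct cannot exceed occurrences")
  if (length(msgs)) msgs else TRUE
})

#' SuffixStructure: suffix array index of a genome
#'
#' Suffix array plus LCP array over the separator-joined runs of a genome
#' (SA-IS construction, Kasai LCP).  LCP values are capped at each suffix's
#' valid length (distance to the next run separator), so repeated words and
#' k-mer groups never span run boundaries.  Supports enumeration of k-mer
#' groups at any k and the maximal repeat length query.
#'
#' @slot sa integer suffix array (0-based positions into the joined text).
#' @slot lcp integer capped LCP array; \code{lcp[i]} refers to suffixes
#'   \code{sa[i-1]}, \code{sa[i]}.
#' @slot valid integer valid length of each suffix, in suffix-array order.
#' @slot n numeric(1) effective genome length.
#' @slot textLength integer(1) length of the joined text (with separators and
#'   sentinel).
#'
#' @seealso [buildSuffixStructure()], [kmerSpectrum()], [mrl()]
#' @exportClass SuffixStructure
setClass("SuffixStructure",
  representation(sa = "integer", lcp = "integer", valid = "integer",
                 n = "numeric", textLength = "integer"))

#' EntropyProfile: empirical k-entropies over a range of k
#'
#' @slot genomeLabel character(1).
#' @slot n numeric(1) effective genome length.
#' @slot k integer vector of word lengths.
#' @slot ek numeric vector of empirical entropies E_k (bits), parallel to k.
#' @slot e2lg numeric(1) entropy interpolated at the double logarithmic length
#'   2LG = lg2(n), or NA when the bracketing k are outside the profile range.
#' @slot k1,k2 integer(1) bracketing integers used for the interpolation
#'   (equal when lg2(n) is an integer).
#'
#' @seealso [entropyProfile()], [interpolatedE2LG()]
#' @exportClass EntropyProfile
setClass("EntropyProfile",
  representation(genomeLabel = "character", n = "numeric", k = "integer",
                 ek = "numeric", e2lg = "numeric", k1 = "integer",
                 k2 = "integer"))

setValidity("EntropyProfile", function(object) {
  if (length(object@k) != length(object@ek))
    return("k and ek must have equal length")
  TRUE
})

#' BBParams: parameters of the biobit complexity function
#'
#' The biobit measure is \code{scale * AF^gamma * (1 - 2 AF)^delta}, where AF
#' is the anti-entropic fraction AC/LG.  \code{delta = 3} weighs the
#' entropic-balance factor; \code{gamma = 0.5} weighs the anti-entropic
#' factor; the multiplicative scale defaults to the genome's logarithmic
#' length LG (set \code{scale = NA} for that behaviour), making BB
#' commensurate with LG.
#'
#' @slot gamma numeric(1) > 0, exponent on AF.
#' @slot delta numeric(1) > 0, exponent on (1 - 2 AF).
#' @slot scale numeric(1), multiplicative constant; NA means "use LG".
#'
#' @seealso [BBParams()], [biobit()], [computeIndexes()]
#' @exportClass BBParams
setClass("BBParams",
  representation(gamma = "numeric", delta = "numeric", scale = "numeric"),
  prototype(gamma = 0.5, delta = 3, scale = NA_real_))

setValidity("BBParams", function(object) {
  if (length(object@gamma) != 1L || !is.finite(object@gamma) || object@gamma <= 0)
    return("gamma must be a single positive number")
  if (length(object@delta) != 1L || !is.finite(object@delta) || object@delta <= 0)
    return("delta must be a single positive number")
  TRUE
})

#' InformationalIndexes: the seven informational indexes of one genome
#'
#' Holds the logarithmic length LG = lg4(n), the double logarithmic length
#' 2LG = lg2(n), the interpolated entropy E_2LG, the entropic component
#' EC = E_2LG - LG, the anti-entropic component AC = 2LG - E_2LG (so that
#' EC + AC = LG), the lexical index LX, the anti-entropic fraction
#' AF = AC/LG, the horizontal eccentricity EH = (EC - AC)/LG = 1 - 2 AF, and
#' the biobit complexity BB.  Also carries the integer-k entropies and
#' lexical ratios used for interpolation and for the derived lexical bound
#' lg2(LX) <= AC at integer k.
#'
#' @slot n,lg,twoLG,e2lg,ec,ac,lx,af,eh,bb numeric(1) index values.
#' @slot k1,k2 integer(1) bracketing word lengths; \code{ek1}, \code{ek2} the
#'   entropies there.
#' @slot kRound integer(1) round(2LG); \code{ekRound}, \code{lxRound} the
#'   entropy and lexical ratio at that integer word length.
#' @slot params the [BBParams-class] used for BB.
#'
#' @seealso [computeIndexes()], [verifyLaws()]
#' @exportClass InformationalIndexes
setClass("InformationalIndexes",
  representation(n = "numeric", lg = "numeric", twoLG = "numeric",
                 e2lg = "numeric", ec = "numeric", ac = "numeric",
                 lx = "numeric", af = "numeric", eh = "numeric",
                 bb = "numeric", k1 = "integer", k2 = "integer",
                 ek1 = "numeric", ek2 = "numeric", kRound = "integer",
                 ekRound = "numeric", lxRound = "numeric",
                 params = "BBParams"))

setValidity("InformationalIndexes", function(object) {
  msgs <- character()
  if (abs(object@ec + object@ac - object@lg) > 1e-9)
    msgs <- c(msgs, "EC + AC must equal LG")
  if (abs(object@twoLG - 2 * object@lg) > 1e-9)
    msgs <- c(msgs, "2LG must equal 2 * LG")
  if (length(msgs)) msgs else TRUE
})

#' EditPlan: genome perturbation plan
#'
#' An ordered set of non-overlapping edit operations in effective (run-space)
#' coordinates, 0-based half-open, interpreted atomically against the genome
#' as it is when the plan is applied.  Supported kinds: \code{"delete"}
#' (remove the span) and \code{"shuffle"} (permute the symbols within the
#' span, using the plan's seed).
#'
#' @slot ops data.frame with columns \code{kind}, \code{start}, \code{length}.
#' @slot seed integer(1) seed for shuffle randomness.
#'
#' @seealso [editPlan()], [applyEdits()], [lawSurvivalScan()]
#' @exportClass EditPlan
setClass("EditPlan",
  representation(ops = "data.frame", seed = "integer"))

setValidity("EditPlan", function(object) {
  ops <- object@ops
  need <- c("kind", "start", "length")
  if (!all(need %in% names(ops)))
    return("ops must have columns kind, start, length")
  if (nrow(ops)) {
    if (!all(ops$kind %in% c("delete", "shuffle")))
      return("op kind must be 'delete' or 'shuffle'")
    if (any(ops$start < 0) || any(ops$length <= 0))
      return("ops must have start >= 0 and length >= 1")
    o <- ops[order(ops$start), , drop = FALSE]
    if (nrow(o) > 1L && any(o$start[-1L] < (o$start + o$length)[-nrow(o)]))
      return("ops within one plan must not overlap")
  }
  TRUE
})

#' LawReport: outcome of checking the informational genomic laws
#'
#' @slot laws data.frame with one row per law: identifier, pass, lhs, rhs,
#'   margin (positive margin = satisfied, with room to spare).
#' @slot overall logical(1): TRUE iff every evaluated law passes.
#'
#' @seealso [verifyLaws()]
#' @exportClass LawReport
setClass("LawReport",
  representation(laws = "data.frame", overall = "logical"))
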