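#' Construct biobit parameters
#'
#' @param gamma positive exponent on the anti-entropic fraction AF
#'   (default 0.5).
#' @param delta positive exponent on the entropic-balance factor (1 - 2 AF)
#'   (default 3).
#' @param scale multiplicative constant; \code{NA} (the default) means "use
#'   the genome's logarithmic length LG".
#' @return a [BBParams-class].
#' @examples
#' BBParams()
#' BBParams(gamma = 1, delta = 1, scale = 1)
#' @export
BBParams <- function(gamma = 0.5, delta = 3, scale = NA_real_) {
  new("BBParams", gamma = as.numeric(gamma), delta = as.numeric(delta),
      scale = as.numeric(scale))
}

setMethod("show", "BBParams", function(object) {
  cat(sprintf("BBParams: gamma = %g, delta = %g, scale = %s\n",
              object@gamma, object@delta,
              ifelse(is.na(object@scale), "LG", format(object@scale))))
})

#' Entropic and anti-entropic components of the logarithmic length
#'
#' Splits LG = lg4(n) into the entropic component EC = E_2LG - LG and the
#' anti-entropic component AC = 2LG - E_2LG, so that EC + AC = LG exactly.
#' For every genuine genome LG < E_2LG < 2LG holds, making both components
#' positive; perturbed or degenerate sequences may violate the inequality, so
#' a violation is reported in the returned \code{withinBounds} flag rather
#' than raised as an error.
#'
#' @param e2lg entropy at the double logarithmic length, in bits.
#' @param n effective genome length.
#' @return list with \code{ec}, \code{ac} and logical \code{withinBounds}.
#' @examples
#' entropicComponents(9, 1024)   # lg = 5, ec = 4, ac = 1
#' @export
entropicComponents <- function(e2lg, n) {
  lg <- logarithmicLength(n)
  ec <- e2lg - lg
  ac <- 2 * lg - e2lg
  list(ec = ec, ac = ac, withinBounds = (e2lg > lg) && (e2lg < 2 * lg))
}

.lxAt <- function(st, k) {
  sp <- .spectrumFromStructure(st, k)
  sp@occurrences / sp@distinct
}

#' Lexical index
#'
#' LX is the ratio between the number of possible word occurrences at the
#' double logarithmic length (which in a random genome equals the number of
#' distinct words, all hapaxes) and the number of distinct words the genome
#' actually uses: LX = W_k / |D_k| at k = 2LG.  A random genome has LX = 1;
#' order and repetitiveness push LX above 1.  For non-integer 2LG the ratio
#' is linearly interpolated between k1 and k2 with the same weights as the
#' entropy interpolation (\code{method = "interpolate"}), or evaluated at
#' round(2LG) (\code{method = "round"}).
#'
#' @param x a [GenomeSequence-class] or [SuffixStructure-class].
#' @param method interpolation rule at non-integer 2LG.
#' @return numeric(1) >= 1.
#' @examples
#' lexicalIndex(generateRandomGenome(5000, seed = 1))  # close to 1
#' @rdname lexicalIndex
#' @export
setMethod("lexicalIndex", "GenomeSequence", function(x, method = c("interpolate", "round")) {
  lexicalIndex(buildSuffixStructure(x), method = method)
})

#' @rdname lexicalIndex
#' @export
setMethod("lexicalIndex", "SuffixStructure", function(x, method = c("interpolate", "round")) {
  method <- match.arg(method)
  br <- .bracket2LG(x@n)
  if (method == "round") {
    .lxAt(x, as.integer(round(br$twoLG)))
  } else if (br$k1 == br$k2) {
    .lxAt(x, br$k1)
  } else {
    .interp2LG(.lxAt(x, br$k1), .lxAt(x, br$k2), x@n)
  }
})

#' The biobit complexity function
#'
#' BB = scale * AF^gamma * (1 - 2 AF)^delta, the weighted-product balance of
#' order (the anti-entropic fraction AF = AC/LG) and randomness (through
#' EH = 1 - 2 AF).  It vanishes at AF = 0 (random-like genomes carry no
#' order) and at AF = 1/2 (super-ordered sequences lose the entropic reserve
#' evolution needs), and has a unique interior maximum at
#' AF* = gamma / (2 gamma + 2 delta).  For AF >= 1/2 the value is returned
#' as a signed magnitude (<= 0), flagging a law-violating sequence.
#'
#' @param af anti-entropic fraction, >= 0 (values >= 0.5 yield <= 0).
#' @param lg logarithmic length, used as the default scale.
#' @param params a [BBParams-class].
#' @return numeric, biobit value(s).
#' @examples
#' biobit(0, lg = 10)                    # 0
#' biobit(0.5, lg = 10)                  # 0
#' biobit(biobitArgmax(), lg = 10)       # the maximum for LG = 10
#' @export
biobit <- function(af, lg, params = BBParams()) {
  if (any(!is.finite(af)) || any(af < 0))
    stop("af must be finite and >= 0")
  scale <- if (is.na(params@scale)) lg else params@scale
  balance <- 1 - 2 * af
  scale * af^params@gamma * sign(balance) * abs(balance)^params@delta
}

#' @rdname biobit
#' @export
biobitArgmax <- function(params = BBParams()) {
  params@gamma / (2 * params@gamma + 2 * params@delta)
}

#' Compute the informational indexes of a genome
#'
#' One-shot pipeline: builds the suffix structure, computes the k-mer spectra
#' and entropies at the bracketing word lengths k1, k2 around 2LG = lg2(n),
#' interpolates E_2LG, and derives LG, EC, AC, LX, AF, EH and BB.  Genomes of
#' at least 16 nucleotides give meaningful indexes (2LG >= 4); shorter or
#' highly degenerate sequences are still processed when the spectra exist,
#' leaving law violations to [verifyLaws()] rather than raising errors, which
#' perturbation experiments rely on.
#'
#' @param genome a [GenomeSequence-class] with n >= 4.
#' @param params a [BBParams-class] for the biobit computation.
#' @param lxMethod lexical-index rule at non-integer 2LG (see
#'   [lexicalIndex()]).
#' @return an [InformationalIndexes-class].
#' @examples
#' ix <- computeIndexes(generateRandomGenome(5000, seed = 7))
#' ix
#' @rdname computeIndexes
#' @export
setMethod("computeIndexes", "GenomeSequence",
          function(genome, params = BBParams(),
                   lxMethod = c("interpolate", "round")) {
  lxMethod <- match.arg(lxMethod)
  validObject(genome)
  n <- genome@n
  if (n < 4)
    stop("genome too short for informational indexes (n < 4)")
  st <- buildSuffixStructure(genome)
  br <- .bracket2LG(n)
  sp1 <- .spectrumFromStructure(st, br$k1)
  ek1 <- empiricalEntropy(sp1)
  if (br$k2 == br$k1) {
    ek2 <- ek1
  } else {
    ek2 <- empiricalEntropy(.spectrumFromStructure(st, br$k2))
  }
  e2lg <- .interp2LG(ek1, ek2, n)
  lg <- logarithmicLength(n)
  comp <- entropicComponents(e2lg, n)
  lx <- lexicalIndex(st, method = lxMethod)
  af <- comp$ac / lg
  eh <- 1 - 2 * af
  bb <- biobit(max(af, 0), lg, params)
  kRound <- as.integer(round(br$twoLG))
  ekRound <- lxRound <- NA_real_
  okRound <- tryCatch({
    spr <- .spectrumFromStructure(st, kRound)
    ekRound <- empiricalEntropy(spr)
    lxRound <- spr@occurrences / spr@distinct
    TRUE
  }, error = function(e) FALSE)
  if (!okRound) kRound <- NA_integer_
  new("InformationalIndexes", n = n, lg = lg, twoLG = br$twoLG,
      e2lg = e2lg, ec = comp$ec, ac = comp$ac, lx = lx, af = af, eh = eh,
      bb = bb, k1 = br$k1, k2 = br$k2, ek1 = ek1, ek2 = ek2,
      kRound = kRound, ekRound = ekRound, lxRound = lxRound,
      params = params)
})

setMethod("show", "InformationalIndexes", function(object) {
  cat(sprintf("InformationalIndexes (n = %s, k1 = %d, k2 = %d):\n",
              format(object@n, big.mark = ","), object@k1, object@k2))
  v <- c(LG = object@lg, EC = object@ec, AC = object@ac, LX = object@lx,
         AF = object@af, EH = object@eh, BB = object@bb)
  for (nm in names(v))
    cat(sprintf("  %-3s %s\n", nm, formatC(v[[nm]], format = "f",
                                           digits = 4)))
})

#' Serialize informational indexes
#'
#' \code{indexesJSON} returns a full-precision JSON object;
#' \code{writeIndexesTSV} writes a one-row TSV in the standard column order
#' LG, EC, AC, LX, AF, EH, BB (values at 4 decimal places, the customary
#' reporting precision).
#'
#' @param ix an [InformationalIndexes-class].
#' @param path output path.
#' @param meta optional named list merged into the JSON output.
#' @return JSON string, or the path invisibly.
#' @export
indexesJSON <- function(ix, meta = NULL) {
  out <- list(n = ix@n, LG = ix@lg, `2LG` = ix@twoLG, E2LG = ix@e2lg,
              EC = ix@ec, AC = ix@ac, LX = ix@lx, AF = ix@af, EH = ix@eh,
              BB = ix@bb, k1 = ix@k1, k2 = ix@k2, E_k1 = ix@ek1,
              E_k2 = ix@ek2,
              bb_params = list(gamma = ix@params@gamma,
                               delta = ix@params@delta,
                               scale = ifelse(is.na(ix@params@scale), "LG",
                                              ix@params@scale)))
  if (!is.null(meta)) out <- c(list(meta = meta), out)
  jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA, na = "null")
}

#' @rdname indexesJSON
#' @export
writeIndexesTSV <- function(ix, path) {
  df <- data.frame(LG = ix@lg, EC = ix@ec, AC = ix@ac, LX = ix@lx,
                   AF = ix@af, EH = ix@eh, BB = ix@bb)
  df[] <- lapply(df, function(x) formatC(x, format = "f", digits = 4))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
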