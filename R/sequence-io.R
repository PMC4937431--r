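#' Construct a GenomeSequence from raw sequence text
#'
#' Normalizes one or more sequence records into the canonical run
#' representation: symbols are lowercased, and every maximal stretch of
#' a/c/g/t within a record becomes one run.  Ambiguity symbols (n, IUPAC
#' codes, gaps) terminate runs and are excluded from the effective length;
#' record boundaries always terminate runs.
#'
#' @param text character vector, one element per sequence record; may contain
#'   ambiguity symbols and mixed case.
#' @param sourceLabel character(1) identifier for the genome.
#' @return a [GenomeSequence-class] object.
#' @examples
#' GenomeSequence("ACGNNACG")           # two runs "acg", "acg"; n = 6
#' GenomeSequence(c("AC", "GT"))        # record boundary splits runs; n = 4
#' @export
GenomeSequence <- function(text, sourceLabel = "") {
  if (length(text) == 0L)
    stop("no sequence records supplied")
  runs <- unlist(strsplit(tolower(paste(text)), "[^acgt]+"))
  runs <- runs[nzchar(runs)]
  if (length(runs) == 0L)
    stop("genome contains no unambiguous a/c/g/t nucleotides")
  new("GenomeSequence", runs = unname(runs), n = sum(nchar(runs)),
      sourceLabel = as.character(sourceLabel)[1L])
}

#' Read a genome from a FASTA file
#'
#' Records are concatenated in file order; each record is normalized as in
#' [GenomeSequence()] (lowercase canonical form, runs split at ambiguity
#' symbols and record boundaries).  Multi-record, wrapped/unwrapped and CRLF
#' FASTA are all accepted, as is plain gzip.
#'
#' @param path path to a readable FASTA file with at least one record.
#' @param sourceLabel identifier recorded in the object; defaults to the file
#'   name.
#' @return a [GenomeSequence-class].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTACGT"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path, sourceLabel = basename(path)) {
  if (!file.exists(path))
    stop("file not found: ", path)
  recs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e)
                     stop("not a readable FASTA file (", conditionMessage(e),
                          "): ", path, call. = FALSE))
  if (length(recs) == 0L)
    stop("FASTA file contains no records: ", path)
  GenomeSequence(as.character(recs), sourceLabel = sourceLabel)
}

#' Write a genome to a FASTA file
#'
#' By default each run becomes one FASTA record (wrapped at 60 columns), so
#' that the file round-trips through [readGenome()] to an equal
#' [GenomeSequence-class].  With \code{collapse = TRUE} the runs are joined
#' into a single record; run boundaries are then lost on re-reading.
#'
#' @param genome a [GenomeSequence-class].
#' @param path output file path.
#' @param collapse write a single record instead of one per run.
#' @param header record name prefix (default derived from the source label).
#' @return the output path, invisibly.
#' @examples
#' g <- GenomeSequence(c("AC", "GT"))
#' fa <- tempfile(fileext = ".fa")
#' writeGenome(g, fa)
#' identical(genomeRuns(readGenome(fa)), genomeRuns(g))
#' @export
writeGenome <- function(genome, path, collapse = FALSE, header = NULL) {
  stopifnot(is(genome, "GenomeSequence"))
  validObject(genome)
  if (is.null(header)) {
    header <- if (nzchar(genome@sourceLabel)) genome@sourceLabel else "genome"
  }
  seqs <- if (collapse) paste(genome@runs, collapse = "") else genome@runs
  dss <- Biostrings::DNAStringSet(seqs)
  names(dss) <- if (length(seqs) == 1L) header
                else sprintf("%s_run%d", header, seq_along(seqs))
  tryCatch(Biostrings::writeXStringSet(dss, filepath = path, width = 60L),
           error = function(e)
             stop("cannot write FASTA to ", path, ": ", conditionMessage(e),
                  call. = FALSE))
  invisible(path)
}

#' @rdname accessors
setMethod("effectiveLength", "GenomeSequence", function(x) x@n)

#' @rdname accessors
setMethod("genomeRuns", "GenomeSequence", function(x) x@runs)

#' @rdname accessors
setMethod("sourceLabel", "GenomeSequence", function(x) x@sourceLabel)

setMethod("show", "GenomeSequence", function(object) {
  cat(sprintf("GenomeSequence '%s': n = %s nucleotides in %d run(s)\n",
              object@sourceLabel, format(object@n, big.mark = ","),
              length(object@runs)))
  preview <- substr(object@runs[1L], 1L, 50L)
  if (nchar(object@runs[1L]) > 50L) preview <- paste0(preview, "...")
  cat("  first run: ", preview, "\n", sep = "")
})
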