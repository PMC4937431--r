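#' Verify the informational genomic laws
#'
#' Evaluates the law set on a genome's computed indexes:
#' \describe{
#'   \item{L1}{LG < E_2LG < 2LG (margin: the smaller distance to a bound).}
#'   \item{L2}{EC > 0 and AC > 0 (the component restatement of L1).}
#'   \item{L3}{EC > AC, equivalently AF < 1/2 and EH > 0 — the condition for
#'     a positive biobit.}
#'   \item{L4}{LX >= 1, with LX = 1 only in the random limit.}
#'   \item{L5}{lg2(LX) <= AC at the integer word length round(2LG), where
#'     AC_k = lg2(n) - E_k.  This is a theorem (it follows from
#'     E_k <= lg2 |D_k| and W_k <= n), so a failure on an unedited genome
#'     indicates an implementation bug; it is checked to a 1e-9 floating
#'     tolerance.}
#' }
#' Failures are data, not exceptions: each law reports pass/fail, the
#' compared values and a signed margin (positive = satisfied).  Additional
#' laws may be registered as functions of the index object returning
#' \code{list(pass, lhs, rhs, margin)}.
#'
#' @param ix an [InformationalIndexes-class].
#' @param extraLaws named list of additional law predicates.
#' @return a [LawReport-class].
#' @examples
#' verifyLaws(computeIndexes(generateRandomGenome(5000, seed = 1)))
#' @rdname verifyLaws
#' @export
setMethod("verifyLaws", "InformationalIndexes",
          function(ix, extraLaws = list()) {
  rows <- list(
    L1 = list(pass = ix@e2lg > ix@lg && ix@e2lg < ix@twoLG,
              lhs = ix@e2lg, rhs = ix@lg,
              margin = min(ix@e2lg - ix@lg, ix@twoLG - ix@e2lg)),
    L2 = list(pass = ix@ec > 0 && ix@ac > 0,
              lhs = ix@ec, rhs = ix@ac, margin = min(ix@ec, ix@ac)),
    L3 = list(pass = ix@ec > ix@ac,
              lhs = ix@ec, rhs = ix@ac, margin = ix@ec - ix@ac),
    L4 = list(pass = ix@lx >= 1,
              lhs = ix@lx, rhs = 1, margin = ix@lx - 1)
  )
  if (!is.na(ix@kRound) && is.finite(ix@lxRound) && is.finite(ix@ekRound)) {
    acK <- log2(ix@n) - ix@ekRound
    rows$L5 <- list(pass = log2(ix@lxRound) <= acK + 1e-9,
                    lhs = log2(ix@lxRound), rhs = acK,
                    margin = acK - log2(ix@lxRound))
  } else {
    rows$L5 <- list(pass = NA, lhs = NA_real_, rhs = NA_real_,
                    margin = NA_real_)
  }
  for (nm in names(extraLaws)) {
    r <- extraLaws[[nm]](ix)
    rows[[nm]] <- list(pass = isTRUE(r$pass), lhs = r$lhs, rhs = r$rhs,
                       margin = r$margin)
  }
  laws <- data.frame(
    law = names(rows),
    pass = vapply(rows, function(r) as.logical(r$pass), logical(1)),
    lhs = vapply(rows, function(r) as.numeric(r$lhs), numeric(1)),
    rhs = vapply(rows, function(r) as.numeric(r$rhs), numeric(1)),
    margin = vapply(rows, function(r) as.numeric(r$margin), numeric(1)),
    row.names = NULL)
  evaluated <- laws$pass[!is.na(laws$pass)]
  new("LawReport", laws = laws, overall = length(evaluated) > 0 &&
        all(evaluated))
})

setMethod("show", "LawReport", function(object) {
  cat("LawReport — overall:", ifelse(object@overall, "PASS", "FAIL"), "\n")
  print(object@laws, row.names = FALSE)
})

#' @rdname verifyLaws
#' @param report a [LawReport-class].
#' @export
lawReportJSON <- function(report) {
  jsonlite::toJSON(list(overall = report@overall, laws = report@laws),
                   auto_unbox = TRUE, digits = NA, na = "null",
                   dataframe = "rows")
}

#' Construct an edit plan
#'
#' @param kind character vector of operation kinds ("delete" or "shuffle").
#' @param start 0-based starts in effective coordinates (ambiguity symbols
#'   are outside the model, so positions count a/c/g/t only).
#' @param length span lengths (half-open intervals \code{[start,
#'   start+length)}).
#' @param seed integer seed driving shuffle randomness.
#' @return an [EditPlan-class].
#' @examples
#' editPlan(kind = c("delete", "shuffle"), start = c(0, 50),
#'          length = c(10, 20), seed = 3)
#' @export
editPlan <- function(kind = character(), start = integer(),
                     length = integer(), seed = 1L) {
  new("EditPlan",
      ops = data.frame(kind = as.character(kind),
                       start = as.numeric(start),
                       length = as.numeric(length)),
      seed = as.integer(seed))
}

setMethod("show", "EditPlan", function(object) {
  cat(sprintf("EditPlan: %d op(s), seed = %d\n", nrow(object@ops),
              object@seed))
  if (nrow(object@ops)) print(object@ops, row.names = FALSE)
})

#' Read and write edit plans as JSON
#'
#' The JSON form is a list of plans, each \code{{"seed": int, "ops":
#' [{"kind": ..., "start": ..., "length": ...}, ...]}}.
#'
#' @param path JSON file path.
#' @param plans list of [EditPlan-class] objects (named list recommended).
#' @return a named list of [EditPlan-class] objects, or the path invisibly.
#' @export
readEditPlans <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE,
                            simplifyVector = FALSE)
  plans <- lapply(raw, function(p) {
    ops <- p$ops
    if (is.null(ops) || (is.list(ops) && length(ops) == 0)) {
      editPlan(seed = if (is.null(p$seed)) 1L else p$seed)
    } else {
      if (!is.data.frame(ops))
        ops <- do.call(rbind, lapply(ops, as.data.frame))
      editPlan(kind = ops$kind, start = ops$start, length = ops$length,
               seed = if (is.null(p$seed)) 1L else p$seed)
    }
  })
  if (!is.null(names(raw))) names(plans) <- names(raw)
  plans
}

#' @rdname readEditPlans
#' @export
writeEditPlans <- function(plans, path) {
  out <- lapply(plans, function(p) list(seed = p@seed, ops = p@ops))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Apply an edit plan to a genome
#'
#' Edits are interpreted atomically against the input genome: all
#' coordinates refer to the effective sequence before any edit, which is
#' well-defined because ops within a plan must not overlap.  Shuffle windows
#' are permuted first (one seeded RNG stream, windows in op order), then
#' deleted spans are removed.  Run boundaries are preserved; runs emptied by
#' deletion disappear.
#'
#' @param genome a [GenomeSequence-class].
#' @param plan an [EditPlan-class] whose spans lie within \code{[0, n)}.
#' @return the edited [GenomeSequence-class].
#' @examples
#' g <- GenomeSequence("ACGTACGTACGT")
#' applyEdits(g, editPlan("delete", start = 0, length = 4))
#' @rdname applyEdits
#' @export
setMethod("applyEdits", signature("GenomeSequence", "EditPlan"),
          function(genome, plan) {
  validObject(genome); validObject(plan)
  ops <- plan@ops
  n <- genome@n
  if (nrow(ops) && any(ops$start + ops$length > n))
    stop("edit operation out of genome bounds [0, ", n, ")")
  chars <- strsplit(genome@runs, "", fixed = TRUE)
  runId <- rep.int(seq_along(chars), lengths(chars))
  chars <- unlist(chars)
  keep <- rep.int(TRUE, n)
  withSeed(plan@seed, {
    for (i in seq_len(nrow(ops))) {
      idx <- seq.int(ops$start[i] + 1L, ops$start[i] + ops$length[i])
      if (ops$kind[i] == "shuffle") {
        chars[idx] <- chars[sample(idx)]
      } else {
        keep[idx] <- FALSE
      }
    }
  })
  if (!any(keep))
    stop("edit plan removes the entire genome")
  runs <- vapply(split(chars[keep], runId[keep]), paste, character(1),
                 collapse = "")
  runs <- unname(runs[nzchar(runs)])
  new("GenomeSequence", runs = runs, n = sum(nchar(runs)),
      sourceLabel = paste0(genome@sourceLabel, "|edited"))
})

#' Law-survival scan over perturbation plans
#'
#' Applies each edit plan to the genome, recomputes the informational
#' indexes and re-checks the laws, collecting one row per plan.  Per-plan
#' failures (e.g. a plan that deletes the whole genome, or leaves it too
#' short for the indexes) are recorded in the \code{error} column and the
#' scan continues.
#'
#' @param genome a [GenomeSequence-class].
#' @param plans list (preferably named) of [EditPlan-class] objects; an
#'   empty plan is the identity.
#' @param params a [BBParams-class] passed to [computeIndexes()].
#' @return data.frame with columns plan, n, LG, EC, AC, LX, AF, EH, BB, the
#'   per-law pass flags, and error.
#' @examples
#' g <- makeFixture("block-mixture", n = 5000, seed = 2,
#'                  orderedFraction = 0.3)
#' plans <- list(identity = editPlan(),
#'               shuffleAll = editPlan("shuffle", 0, 5000, seed = 9))
#' lawSurvivalScan(g, plans)
#' @export
lawSurvivalScan <- function(genome, plans, params = BBParams()) {
  if (is.null(names(plans)))
    names(plans) <- sprintf("plan%d", seq_along(plans))
  lawIds <- c("L1", "L2", "L3", "L4", "L5")
  rows <- lapply(names(plans), function(nm) {
    base <- data.frame(plan = nm, n = NA_real_, LG = NA_real_,
                       EC = NA_real_, AC = NA_real_, LX = NA_real_,
                       AF = NA_real_, EH = NA_real_, BB = NA_real_)
    for (l in lawIds) base[[l]] <- NA
    base$error <- NA_character_
    tryCatch({
      edited <- applyEdits(genome, plans[[nm]])
      ix <- computeIndexes(edited, params = params)
      rep <- verifyLaws(ix)
      base$n <- ix@n; base$LG <- ix@lg; base$EC <- ix@ec; base$AC <- ix@ac
      base$LX <- ix@lx; base$AF <- ix@af; base$EH <- ix@eh; base$BB <- ix@bb
      for (l in lawIds)
        base[[l]] <- rep@laws$pass[rep@laws$law == l]
      base
    }, error = function(e) {
      base$error <- conditionMessage(e)
      base
    })
  })
  do.call(rbind, rows)
}
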