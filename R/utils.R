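# internal helpers

#' Evaluate an expression under a local RNG stream
#'
#' Runs \code{expr} after seeding the random number generator with
#' \code{seed}, then restores the caller's RNG state, so seeded helpers never
#' disturb an enclosing simulation.  With \code{seed = NULL} the expression
#' is evaluated under the current stream.
#'
#' @param seed integer seed, or NULL for no reseeding.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @examples
#' set.seed(1); x <- runif(1)
#' set.seed(1); y <- withSeed(99, runif(5))
#' stopifnot(identical(runif(1), x))  # caller's stream unaffected
#' @export
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
    on.exit({
      if (had) assign(".Random.seed", old, envir = genv)
      else if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
  }
  force(expr)
}

# iid uniform nucleotide codes 1..4 (a, c, g, t)
.randomCodes <- function(n, seed = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    stop("n must be a positive integer")
  withSeed(seed, sample.int(4L, as.integer(n), replace = TRUE))
}

.codesToString <- function(codes) {
  # 97, 99, 103, 116 = utf8 'a', 'c', 'g', 't'
  intToUtf8(c(97L, 99L, 103L, 116L)[codes])
}

.assertScalarCount <- function(x, name, min = 1) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != floor(x))
    stop(sprintf("%s must be a single integer >= %s", name, format(min)))
  invisible(as.integer(x))
}
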