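## Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' All stochastic operations in the package accept a `seed` argument and route
#' it through this helper: with a seed the expression sees a freshly seeded
#' Mersenne-Twister stream and the caller's RNG state is restored afterwards;
#' with `seed = NULL` the expression consumes the current stream (used
#' internally so that one top-level seed drives a whole analysis).
#'
#' @param seed integer or NULL.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

## sample() without its length-1 surprise
.sampleFrom <- function(x, size, prob = NULL) {
  x[sample.int(length(x), size, replace = FALSE, prob = prob)]
}

.assertCountVector <- function(x, what = "counts") {
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop(what, " must be a named vector with unique names")
  if (any(x < 0) || any(x != round(x)))
    stop(what, " must be non-negative integers")
  invisible(x)
}

.assertAbundance <- function(p, tol = 1e-9) {
  if (any(p < 0)) stop("abundances must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop("abundances must sum to 1 (observed sum ", format(sum(p)), ")")
  invisible(p)
}

## Deterministic hash of an R object, via its canonical serialization.
.hashObject <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
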