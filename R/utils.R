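#' @importFrom stats rgamma setNames sd
#' @importFrom utils write.csv read.csv
NULL

## Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
## .Random.seed is untouched. `seed = NULL` uses the current stream.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## log with a probability floor; deterministic (zero-entry) matrices are
## first-class inputs, so ln 0 must stay finite.
flooredLog <- function(p, logFloor = 1e-16) {
  log(pmax(p, logFloor))
}

## entropy-style sum with the 0 * log(0) = 0 convention
xlogx <- function(p) {
  sum(ifelse(p > 0, p * log(p), 0))
}

assertProbabilityVector <- function(p, what = "probability vector",
                                    tol = 1e-8) {
  if (!is.numeric(p) || any(!is.finite(p)))
    stop(what, " must be finite numeric", call. = FALSE)
  if (any(p < -tol) || abs(sum(p) - 1) > tol)
    stop(what, " must be non-negative and sum to 1", call. = FALSE)
  invisible(TRUE)
}

assertCount <- function(x, what, minimum = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < minimum)
    stop("'", what, "' must be a single integer >= ", minimum, call. = FALSE)
  invisible(as.integer(x))
}
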