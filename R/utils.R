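# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package functions do not
#' perturb the caller's random stream. With `seed = NULL` the expression runs
#' on the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Standardize a vector to zero mean, unit standard deviation
#' @noRd
standardize <- function(x) {
  s <- sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize a zero-variance series", call. = FALSE)
  (x - mean(x)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
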