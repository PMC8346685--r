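#' @useDynLib roiclass, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rbinom rgamma var sd cor quantile predict
#' @importFrom utils head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed` so that seeded internals
#' never disturb the global RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

#' Derive a stream of per-stage seeds from a master seed
#'
#' Deterministic, order-stable, and keeps every derived seed within the
#' 32-bit signed integer range expected by [set.seed()].
#' @noRd
derive_seeds <- function(master_seed, n, salt = 0L) {
  with_seed((abs(master_seed) + 1000003 * abs(salt)) %% 2147483647,
            sample.int(2147483646L, n))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
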