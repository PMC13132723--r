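#' Derive a child seed from a global seed and a stream key
#'
#' All stochastic operations in the package fan a single integer seed out into
#' named child streams, so that e.g. adding a brain region to a simulated
#' cohort does not perturb the random draws of the other regions.
#'
#' @param seed integer global seed.
#' @param key character scalar naming the stream (e.g. `"cortex|MG"`).
#' @return An integer in `[0, 2^31 - 2]`, deterministic in `(seed, key)`.
#' @examples
#' child_seed(42L, "cortex|MG")
#' @export
child_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key), length(key) == 1L)
  codes <- utf8ToInt(key)
  # order-sensitive polynomial hash, kept in double precision below 2^53
  m <- 2147483647
  h <- 0
  for (cd in codes) h <- (h * 131 + cd) %% m
  as.integer((((abs(seed) %% m) * 48271) %% m + h) %% m)
}

#' Evaluate an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed`, so seeded internals never disturb the
#' caller's RNG state.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
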