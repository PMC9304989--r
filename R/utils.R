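#' Derive a child seed from a root seed
#'
#' Every stochastic stage of the pipeline receives its own seed derived
#' deterministically from one root seed, so that a single integer reproduces
#' a whole experiment while independent stages (event simulation, network
#' initialization, batch schedule, k-means++ draws) use decoupled streams.
#' The derivation is a fixed LCG-style hash; collisions between distinct
#' `(seed, key)` pairs are astronomically unlikely to matter at the scales
#' used here.
#'
#' @param seed integer-like root seed.
#' @param key integer stream key (stage or event index).
#' @return A numeric scalar in `[1, 2^31 - 1]`, exact in double precision.
#' @export
derive_seed <- function(seed, key = 0L) {
  seed <- as.numeric(seed) %% 2147483647
  key <- as.numeric(key) %% 2147483647
  x <- (seed * 69069 + key * 12345 + 1) %% 2147483647
  x <- (x * 69069 + 97) %% 2147483647
  x + 1
}

#' Evaluate code with a temporary RNG state
#'
#' Seeds R's RNG, runs `expr`, and restores the previous global RNG state so
#' library functions that consume `.Random.seed` stay reproducible without
#' clobbering the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

stop_if_not_scalar_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("`%s` must be a single positive number", name), call. = FALSE)
  invisible(x)
}
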