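#' Derive a child seed from a master seed
#'
#' All randomness in holostiff flows through explicit integer seeds.  Child
#' streams (one per scene in an ensemble, one per frame in a stack, ...) are
#' derived deterministically from the master seed by counter, never from
#' global RNG state, so any sub-object can be regenerated in isolation.
#'
#' @param seed master seed, a single finite number (used modulo 2^31 - 1)
#' @param i counter (non-negative integer); distinct counters give distinct,
#'   reproducible child seeds
#' @return a single integer in \code{[1, 2^31 - 2]}
#' @export
child_seed <- function(seed, i) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(i), length(i) == 1L, i >= 0)
  m <- 2147483647 # 2^31 - 1, prime
  s <- (abs(seed) %% m)
  # two rounds of a Lehmer-style mix keep counters well separated
  s <- (s * 48271) %% m
  s <- (s + (i %% m) * 69621) %% m
  s <- (s * 16807) %% m
  as.integer(s %% (m - 2) + 1)
}

# Evaluate expr with a local RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}
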