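#' Derive a reproducible sub-seed from a master seed
#'
#' All randomness in a study flows from one master seed through named
#' sub-seeds so each stage (cohort, noise, folds, weight init, shuffling)
#' can be audited independently.  The derivation is a small multiplicative
#' hash of the master seed and the tag, kept below 2^31 - 1 so the result is
#' always a valid R integer seed.
#'
#' @param master integer master seed.
#' @param tag character label of the consumer, e.g. "cohort" or "fold".
#' @param index optional integer distinguishing repeated consumers.
#' @return a single integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, tag, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(tag))
  m <- 2147483647 # 2^31 - 1, prime
  h <- (abs(master) %% m)
  for (ch in utf8ToInt(tag)) h <- (h * 131 + ch) %% m
  h <- (h * 131 + (abs(index) %% m)) %% m
  as.integer(h)
}

# internal: run expr with a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# internal: clip values to a symmetric range
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# internal: stop with a formatted message
fail <- function(...) stop(sprintf(...), call. = FALSE)
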