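# Internal helpers: seed management and lightweight logging.

#' Derive a child seed from a master seed
#'
#' Deterministically spawns per-stage / per-iteration seeds from one master
#' seed so that adding iterations never changes earlier ones. The derivation
#' is a multiplicative-congruential step keyed by an integer or string label,
#' kept inside the 32-bit signed range R requires of [set.seed()].
#'
#' @param seed master seed (single integer).
#' @param key integer index or character label of the child stream.
#' @return A single integer usable with [set.seed()].
#' @export
child_seed <- function(seed, key) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  if (is.character(key)) {
    key <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  }
  m <- 2147483647  # 2^31 - 1
  x <- (as.numeric(seed) %% m)
  x <- (x * 48271 + as.numeric(key) * 69621 + 1) %% m
  as.integer(x)
}

# Evaluate `expr` with the RNG set to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user-level randomness.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Per-stage structured log: a character vector of "key: value" lines kept as
# an attribute on results, so filter funnels (probes removed, samples
# excluded, genes intersected, edges pruned) stay auditable.
log_line <- function(...) {
  msg <- paste0(...)
  if (isTRUE(getOption("minregnet.verbose", FALSE))) message(msg)
  msg
}
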