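#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`,
#' and restores the previous state on exit. Used so that constructors
#' taking a `seed` argument are reproducible without clobbering the
#' session RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a stream of child seeds from a master seed
#'
#' @param seed master integer seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds, each in [1, 2^31 - 2].
#' @export
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# uniform tie-broken argmax (draws from the ambient RNG only on ties)
argmax_tie <- function(x) {
  m <- which(x == max(x))
  if (length(m) == 1L) m else m[sample.int(length(m), 1L)]
}
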