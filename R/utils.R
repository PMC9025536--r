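#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals (training-set
#' balancing, forest growing, noise synthesis) never disturb the caller's
#' random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 32-bit sub-seed from a base seed and a character key.
# Keyed by patient id so per-fold randomness is invariant to patient order.
derive_seed <- function(seed, key) {
  h <- 0
  for (v in utf8ToInt(as.character(key))) h <- (h * 31 + v) %% 1000000007
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_finite <- function(x, what = "input") {
  if (!all(is.finite(x))) stop_invalid(what, " contains non-finite values")
  invisible(x)
}
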