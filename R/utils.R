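#' @useDynLib shockpipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import data.table
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a master seed and a stream label
#'
#' One master seed governs a run; every stochastic stage draws from its own
#' child stream so that adding a stage never perturbs the draws of another.
#' The derivation is a fixed integer mix of the master seed, the UTF-8 bytes
#' of the label and an optional index, reduced modulo 2^31 - 1.
#'
#' @param seed master seed (single integer).
#' @param label character stream label, e.g. `"mice"` or `"mcar"`.
#' @param index optional integer sub-index (e.g. chain number).
#' @return an integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
child_seed <- function(seed, label, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- (as.double(seed) %% m)
  for (b in utf8ToInt(label)) h <- (h * 131 + b) %% m
  h <- (h * 131 + as.double(index) + 17) %% m
  as.integer(h %% (m - 2) + 1)
}

#' Evaluate an expression under a local RNG state
#'
#' Saves and restores `.Random.seed` so library internals never disturb the
#' caller's stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

assert_prob_vector <- function(p, what, tol = 1e-12) {
  if (any(p < 0)) stop(what, ": probabilities must be non-negative")
  if (abs(sum(p) - 1) > tol)
    stop(what, ": probabilities must sum to 1 (got ", format(sum(p)), ")")
  invisible(p)
}
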