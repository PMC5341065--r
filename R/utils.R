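#' Run an expression with a local random seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the global
#' `.Random.seed` afterwards, so stochastic operations never leak state.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a named sub-seed from a master seed
#'
#' Deterministically maps (master seed, stream name) to an integer in
#' `[1, 2^31 - 2]`, so pipeline stages get independent, reproducible
#' random streams.
#'
#' @param seed master integer seed.
#' @param name character stream name, e.g. "refine-unfolded".
#' @return an integer seed.
#' @export
derive_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.double(seed) %% m
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  as.integer(h %% (m - 1)) + 1L
}

# stop() unless all pairwise-equal numeric grids
.same_grid <- function(qa, qb, tol = 1e-9) {
  length(qa) == length(qb) && all(abs(qa - qb) <= tol * pmax(1, abs(qa)))
}

.is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x == round(x)
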