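# internal helpers shared across modules

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded helpers (fold splitting, data generation) never
#' disturb an optimizer's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# squared Euclidean distances between all rows of X (n x n, clamped at 0)
pairwise_sqdist <- function(X) {
  X <- as.matrix(X)
  sq <- rowSums(X * X)
  D <- outer(sq, sq, "+") - 2 * tcrossprod(X)
  D[D < 0] <- 0
  D
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
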