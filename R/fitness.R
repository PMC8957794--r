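# The wrapper-selection objective: cross-validated KNN error traded against
# relative subset size.

#' Fitness configuration
#'
#' Parameters of the selection objective. The fitness of a candidate subset
#' is `beta * ER + (1 - beta) * |SF| / |AF|`, where `ER` is the k-fold
#' cross-validated error rate of a k-nearest-neighbour classifier restricted
#' to the selected columns, `|SF|` the number of selected features and
#' `|AF|` the total number of features. `beta = 0.99` puts nearly all weight
#' on classification performance; the small size term breaks ties in favour
#' of leaner subsets.
#'
#' @param beta weight of the error term, in `[0, 1]`; default 0.99.
#' @param knn_k neighbourhood size of the internal KNN; default 5.
#' @param n_folds folds of the internal cross-validation; default 5.
#' @param fold_seed seed from which the (fixed) internal folds are drawn.
#' @param stratified stratify the internal folds by class; default `TRUE`.
#' @return an object of class `FitnessConfig`.
#' @export
fitness_config <- function(beta = 0.99, knn_k = 5, n_folds = 5, fold_seed = 1,
                           stratified = TRUE) {
  if (beta < 0 || beta > 1) stop_validation("beta must be in [0, 1]")
  if (knn_k < 1) stop_validation("knn_k must be >= 1")
  if (n_folds < 2) stop_validation("n_folds must be >= 2")
  structure(list(beta = beta, knn_k = as.integer(knn_k),
                 n_folds = as.integer(n_folds),
                 fold_seed = as.integer(fold_seed),
                 stratified = isTRUE(stratified)),
            class = "FitnessConfig")
}

fitness_folds <- function(m, cfg) {
  kfold_split(n_samples(m), m$labels, cfg$n_folds, cfg$fold_seed,
              cfg$stratified)
}

#' Cross-validated KNN error rate of a feature subset
#'
#' Mean over folds of the fraction of misclassified test samples, using a
#' k-nearest-neighbour classifier (Euclidean distance on the selected
#' columns only) trained on the remaining folds. Deterministic given the
#' configuration: folds come from `cfg$fold_seed` and all KNN ties break by
#' lowest training-sample index.
#'
#' @param mask logical feature-inclusion vector with at least one `TRUE`.
#' @param m a [feature_matrix()] without missing values.
#' @param cfg a [fitness_config()].
#' @param folds optional precomputed fold list (as from [kfold_split()]);
#'   by default derived from `cfg`.
#' @return error rate in `[0, 1]`.
#' @export
error_rate <- function(mask, m, cfg = fitness_config(), folds = NULL) {
  mask <- assert_mask(mask, n_features(m))
  if (!any(mask)) stop_validation("error_rate needs a non-empty mask")
  folds <- folds %||% fitness_folds(m, cfg)
  D <- pairwise_sqdist(m$values[, mask, drop = FALSE])
  knn_cv_error(D, m$labels, folds, cfg$knn_k)
}

#' Combine an error rate and a subset size into a fitness value
#'
#' @param er classification error rate in `[0, 1]`.
#' @param n_selected number of selected features, `|SF|`.
#' @param n_total total number of features, `|AF|`.
#' @param beta weight of the error term.
#' @return `beta * er + (1 - beta) * n_selected / n_total`, or 1 (the worst
#'   possible value) when `n_selected` is 0.
#' @export
fitness_from_error <- function(er, n_selected, n_total, beta = 0.99) {
  if (n_selected == 0) return(1)
  beta * er + (1 - beta) * (n_selected / n_total)
}

#' Fitness of a feature subset
#'
#' The scalar objective minimised by the optimizers; see [fitness_config()]
#' for the formula. An empty mask gets the maximal penalty 1 so the search
#' is repelled from the degenerate all-zero subset.
#'
#' @inheritParams error_rate
#' @param cache optional environment used to memoise fitness by mask bits
#'   (see [new_fitness_cache()]); threshold binarization makes repeated
#'   masks common, so caching pays off inside optimizer runs.
#' @return fitness in `[0, 1]`.
#' @export
fitness <- function(mask, m, cfg = fitness_config(), folds = NULL,
                    cache = NULL) {
  mask <- assert_mask(mask, n_features(m))
  if (!any(mask)) return(1)
  if (!is.null(cache)) {
    key <- mask_key(mask)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  er <- error_rate(mask, m, cfg, folds = folds)
  val <- fitness_from_error(er, sum(mask), length(mask), cfg$beta)
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Create an empty fitness cache
#'
#' @return a hashed environment suitable for the `cache` argument of
#'   [fitness()] and [swarm_optimize()].
#' @export
new_fitness_cache <- function() new.env(hash = TRUE, parent = emptyenv())

mask_key <- function(mask) {
  pad <- (8 - length(mask) %% 8) %% 8
  paste(packBits(c(mask, rep(FALSE, pad)), type = "raw"), collapse = "")
}

#' Exhaustively evaluate every non-empty feature subset
#'
#' Brute-force search over all `2^d - 1` masks; practical only for small
#' feature counts (`d <= 20`). Used as a ground-truth optimum for validating
#' the stochastic optimizers on tiny search spaces.
#'
#' @inheritParams fitness
#' @param max_d guard against accidental exponential blow-up; default 20.
#' @return list with `best_mask`, `best_fitness`, and `n_evaluated`. When a
#'   `cache` is supplied every evaluated mask is stored in it.
#' @export
exhaustive_search <- function(m, cfg = fitness_config(), cache = NULL,
                              max_d = 20) {
  d <- n_features(m)
  if (d > max_d)
    stop_validation("exhaustive search over %d features is intractable", d)
  folds <- fitness_folds(m, cfg)
  best <- Inf
  best_mask <- NULL
  for (code in seq_len(2^d - 1)) {
    mask <- as.logical(bitwAnd(bitwShiftR(code, 0:(d - 1)), 1L))
    f <- fitness(mask, m, cfg, folds = folds, cache = cache)
    if (f < best) {
      best <- f
      best_mask <- mask
    }
  }
  list(best_mask = best_mask, best_fitness = best, n_evaluated = 2^d - 1)
}
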