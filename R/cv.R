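# Cross-validation fold construction.

#' Stratified k-fold split
#'
#' Partitions `1:n_samples` into `k` disjoint test sets of near-equal size.
#' With `stratified = TRUE` (default) each class is dealt round-robin across
#' folds so per-class counts differ by at most one between folds, mirroring
#' the usual requirement that fold label distributions match the full data.
#' Classes with fewer members than `k` simply contribute to a subset of the
#' folds (stratification degrades gracefully, with a warning).
#'
#' @param n_samples number of samples.
#' @param labels class labels (length `n_samples`); ignored when
#'   `stratified = FALSE`.
#' @param k number of folds.
#' @param seed integer; folds are a deterministic function of the seed and
#'   the caller's RNG state is left untouched.
#' @param stratified logical, default `TRUE`.
#' @return list of `k` integer vectors of test indices: pairwise disjoint,
#'   jointly covering `1:n_samples`, sizes differing by at most one.
#' @export
kfold_split <- function(n_samples, labels = NULL, k = 5, seed = 1,
                        stratified = TRUE) {
  if (k > n_samples)
    stop_validation("k = %d folds but only %d samples", k, n_samples)
  if (k < 2) stop_validation("k must be at least 2")
  if (stratified && is.null(labels))
    stop_validation("stratified splitting needs labels")
  folds <- vector("list", k)
  with_seed(seed, {
    if (stratified) {
      labels <- factor(labels)
      if (any(table(labels) < k))
        warning("some classes have fewer members than folds; ",
                "stratification is partial", call. = FALSE)
      offset <- 0L
      for (lv in levels(labels)) {
        idx <- which(labels == lv)
        idx <- idx[sample.int(length(idx))]
        # rolling offset keeps total fold sizes balanced across classes
        fold_of <- ((seq_along(idx) - 1L + offset) %% k) + 1L
        for (f in seq_len(k))
          folds[[f]] <- c(folds[[f]], idx[fold_of == f])
        offset <- (offset + length(idx)) %% k
      }
    } else {
      idx <- sample.int(n_samples)
      fold_of <- ((seq_len(n_samples) - 1L) %% k) + 1L
      for (f in seq_len(k)) folds[[f]] <- idx[fold_of == f]
    }
  })
  lapply(folds, sort)
}

#' Leave-one-out split
#'
#' @param n_samples number of samples (at least 2).
#' @return list of `n_samples` singleton test-index sets.
#' @export
loocv_split <- function(n_samples) {
  if (n_samples < 2) stop_validation("LOOCV needs at least 2 samples")
  lapply(seq_len(n_samples), identity)
}
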