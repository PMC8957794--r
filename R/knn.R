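# Deterministic k-nearest-neighbour classifier.
#
# All tie-breaks are by lowest training-sample index: equal distances are
# ordered by index, and a tied vote goes to the class of the lowest-index
# neighbour among the tied classes. This makes every evaluation
# bit-reproducible.

# predict labels for test rows given a (n_test x n_train) squared-distance
# matrix and the training labels (factor); returns factor of test predictions
knn_predict_dist <- function(D, train_labels, k) {
  k <- min(k, ncol(D))
  out <- integer(nrow(D))
  lab <- as.integer(train_labels)
  for (i in seq_len(nrow(D))) {
    ord <- order(D[i, ], seq_len(ncol(D)))[seq_len(k)]
    votes <- tabulate(lab[ord], nbins = nlevels(train_labels))
    top <- which(votes == max(votes))
    if (length(top) > 1L) {
      # class of the lowest-index neighbour among tied classes
      neigh <- sort(ord)
      top <- lab[neigh[lab[neigh] %in% top][1L]]
    }
    out[i] <- top
  }
  factor(levels(train_labels)[out], levels = levels(train_labels))
}

# KNN misclassification over CV folds, given a precomputed full n x n
# squared-distance matrix on the selected features. Returns the mean over
# folds of the per-fold error rate.
knn_cv_error <- function(D, labels, folds, k) {
  labels <- factor(labels)
  errs <- vapply(folds, function(test) {
    train <- setdiff(seq_along(labels), test)
    pred <- knn_predict_dist(D[test, train, drop = FALSE], labels[train], k)
    mean(pred != labels[test])
  }, numeric(1))
  mean(errs)
}

# positive-class vote fraction for AUC scoring
knn_scores_dist <- function(D, train_labels, k, positive) {
  k <- min(k, ncol(D))
  pos <- as.character(train_labels) == positive
  vapply(seq_len(nrow(D)), function(i) {
    ord <- order(D[i, ], seq_len(ncol(D)))[seq_len(k)]
    mean(pos[ord])
  }, numeric(1))
}
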