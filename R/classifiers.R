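# Multi-classifier evaluation of a selected feature subset.
#
# Five classifier families are supported, concretised as:
#   SVM - soft-margin support vector machine, RBF kernel (e1071::svm)
#   KNN - k-nearest neighbours, k = 5, deterministic tie-breaks (internal)
#   DA  - linear discriminant analysis (MASS::lda)
#   EoL - ensemble of learners: bagged decision trees, 50 rpart learners
#   NB  - Gaussian naive Bayes (e1071::naiveBayes)
#
# Predictions are pooled over CV folds; binary tasks get the full metric
# suite (accuracy, precision, recall, F1, rank-based AUC), multiclass tasks
# get accuracy only.

CLASSIFIERS <- c("SVM", "KNN", "DA", "EoL", "NB")

#' Evaluate classifiers on a feature subset
#'
#' Restricts the matrix to the selected columns, runs cross-validation,
#' pools the per-fold test predictions, and computes the metric suite per
#' classifier. The positive class of a binary task defaults to the
#' lexicographically larger label. AUC is the rank statistic
#' (Mann-Whitney) on pooled continuous scores: signed decision values for
#' SVM, positive-class posterior for DA and NB, positive vote fraction for
#' KNN and the bagged-tree ensemble.
#'
#' @param mask logical feature-inclusion vector (non-empty).
#' @param m a [feature_matrix()] without missing values.
#' @param classifiers subset of `c("SVM", "KNN", "DA", "EoL", "NB")`.
#' @param cv either `list(type = "kfold", k = 5, seed = 1)` or
#'   `list(type = "loocv")`.
#' @param positive label treated as positive in binary metrics; default the
#'   lexicographically larger level.
#' @param knn_k neighbourhood size for the KNN classifier; default 5.
#' @param eol_learners number of bagged trees in the ensemble; default 50.
#' @param eol_seed seed for the bagging resamples; default 1.
#' @return an `EvaluationReport`: list with one entry per classifier
#'   (`accuracy`, `precision`, `recall`, `f1`, `auc_roc`, `confusion`,
#'   `per_fold_accuracy`, `skipped_folds`), plus attributes `positive` and
#'   `task` (`"binary"` or `"multiclass"`).
#' @export
evaluate_classifiers <- function(mask, m,
                                 classifiers = CLASSIFIERS,
                                 cv = list(type = "kfold", k = 5, seed = 1),
                                 positive = NULL,
                                 knn_k = 5,
                                 eol_learners = 50,
                                 eol_seed = 1) {
  mask <- assert_mask(mask, n_features(m))
  if (!any(mask)) stop_validation("evaluate_classifiers needs a non-empty mask")
  classifiers <- match.arg(classifiers, CLASSIFIERS, several.ok = TRUE)
  X <- m$values[, mask, drop = FALSE]
  y <- droplevels(factor(m$labels))
  binary <- nlevels(y) == 2
  if (binary) {
    positive <- positive %||% max(levels(y))
    if (!positive %in% levels(y))
      stop_validation("positive label '%s' is not a class label", positive)
  }
  folds <- switch(cv$type %||% "kfold",
    kfold = kfold_split(nrow(X), y, cv$k %||% 5, cv$seed %||% 1),
    loocv = loocv_split(nrow(X)),
    stop_validation("unknown cv type '%s'", cv$type)
  )
  report <- list()
  for (cl in classifiers) {
    pred <- factor(rep(NA_character_, nrow(X)), levels = levels(y))
    score <- rep(NA_real_, nrow(X))
    fold_acc <- rep(NA_real_, length(folds))
    skipped <- integer(0)
    for (f in seq_along(folds)) {
      test <- folds[[f]]
      train <- setdiff(seq_len(nrow(X)), test)
      if (nlevels(droplevels(y[train])) < 2) {
        warning(sprintf("%s: fold %d skipped (single-class training set)",
                        cl, f), call. = FALSE)
        skipped <- c(skipped, f)
        next
      }
      fit <- fit_predict(cl, X[train, , drop = FALSE], y[train],
                         X[test, , drop = FALSE],
                         positive = if (binary) positive else NULL,
                         knn_k = knn_k, eol_learners = eol_learners,
                         eol_seed = eol_seed + f)
      pred[test] <- fit$pred
      if (binary) score[test] <- fit$score
      fold_acc[f] <- mean(fit$pred == y[test])
    }
    seen <- !is.na(pred)
    acc <- mean(pred[seen] == y[seen])
    entry <- list(accuracy = acc, per_fold_accuracy = fold_acc,
                  skipped_folds = skipped)
    if (binary) {
      cc <- confusion_counts(y[seen], pred[seen], positive)
      entry$confusion <- cc
      entry <- c(entry, binary_metrics(cc))
      entry$auc_roc <- rank_auc(score[seen],
                                as.character(y[seen]) == positive)
    }
    report[[cl]] <- entry
  }
  structure(report, class = "EvaluationReport",
            positive = if (binary) positive else NA_character_,
            task = if (binary) "binary" else "multiclass")
}

fit_predict <- function(classifier, Xtr, ytr, Xte, positive,
                        knn_k, eol_learners, eol_seed) {
  ytr <- droplevels(ytr)
  switch(classifier,
    SVM = {
      fit <- e1071::svm(Xtr, ytr, kernel = "radial", scale = FALSE)
      pr <- stats::predict(fit, Xte, decision.values = TRUE)
      score <- NULL
      if (!is.null(positive)) {
        dv <- attr(pr, "decision.values")
        # orient the decision value so larger means "more positive"
        sgn <- if (startsWith(colnames(dv)[1], paste0(positive, "/"))) 1 else -1
        score <- sgn * dv[, 1]
      }
      list(pred = pr, score = score)
    },
    KNN = {
      D <- sq_cross_dist(Xte, Xtr)
      list(pred = knn_predict_dist(D, ytr, knn_k),
           score = if (is.null(positive)) NULL
                   else knn_scores_dist(D, ytr, knn_k, positive))
    },
    DA = {
      keep <- apply(Xtr, 2, function(v) stats::sd(v) > 0)
      if (!any(keep)) stop_validation("DA: all features constant in training fold")
      fit <- MASS::lda(Xtr[, keep, drop = FALSE], grouping = ytr)
      pr <- stats::predict(fit, Xte[, keep, drop = FALSE])
      list(pred = pr$class,
           score = if (is.null(positive)) NULL else pr$posterior[, positive])
    },
    EoL = {
      bagged_trees_predict(Xtr, ytr, Xte, positive, eol_learners, eol_seed)
    },
    NB = {
      fit <- e1071::naiveBayes(Xtr, ytr)
      pred <- stats::predict(fit, Xte, type = "class")
      score <- NULL
      if (!is.null(positive)) {
        post <- stats::predict(fit, Xte, type = "raw")
        score <- post[, positive]
      }
      list(pred = pred, score = score)
    }
  )
}

# bagged CART ensemble: majority vote of trees grown on bootstrap resamples
bagged_trees_predict <- function(Xtr, ytr, Xte, positive, n_learners, seed) {
  dtr <- data.frame(.y = ytr, Xtr, check.names = FALSE)
  dte <- data.frame(Xte, check.names = FALSE)
  votes <- matrix(0, nrow(Xte), nlevels(ytr),
                  dimnames = list(NULL, levels(ytr)))
  with_seed(seed, {
    for (b in seq_len(n_learners)) {
      idx <- sample.int(nrow(Xtr), replace = TRUE)
      if (nlevels(droplevels(ytr[idx])) < 2) next
      tree <- rpart::rpart(.y ~ ., data = dtr[idx, , drop = FALSE],
                           method = "class",
                           control = rpart::rpart.control(minsplit = 2,
                                                          cp = 0))
      pr <- stats::predict(tree, dte, type = "class")
      votes[cbind(seq_len(nrow(Xte)), as.integer(pr))] <-
        votes[cbind(seq_len(nrow(Xte)), as.integer(pr))] + 1
    }
  })
  pred <- factor(levels(ytr)[max.col(votes, ties.method = "first")],
                 levels = levels(ytr))
  total <- pmax(rowSums(votes), 1)
  list(pred = pred,
       score = if (is.null(positive)) NULL else votes[, positive] / total)
}

sq_cross_dist <- function(A, B) {
  D <- outer(rowSums(A * A), rowSums(B * B), "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

#' Confusion counts for a binary task
#'
#' @param truth,pred factors of true and predicted labels.
#' @param positive label counted as positive.
#' @return named vector `c(TP, FP, TN, FN)`.
#' @export
confusion_counts <- function(truth, pred, positive) {
  tpos <- as.character(truth) == positive
  ppos <- as.character(pred) == positive
  c(TP = sum(tpos & ppos), FP = sum(!tpos & ppos),
    TN = sum(!tpos & !ppos), FN = sum(tpos & !ppos))
}

#' Accuracy, precision, recall, and F1 from confusion counts
#'
#' Accuracy is `(TP + TN) / (TP + FP + TN + FN)`. F1 is defined as 0 when
#' precision and recall are both 0.
#'
#' @param cc named counts as from [confusion_counts()].
#' @return list with `accuracy`, `precision`, `recall`, `f1`.
#' @export
binary_metrics <- function(cc) {
  tp <- cc[["TP"]]; fp <- cc[["FP"]]; tn <- cc[["TN"]]; fn <- cc[["FN"]]
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = (tp + tn) / (tp + fp + tn + fn),
       precision = precision, recall = recall, f1 = f1)
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic on
#' average ranks of the scores, equivalent to the probability that a random
#' positive outranks a random negative (ties counted half).
#'
#' @param scores numeric scores, larger meaning more positive.
#' @param is_positive logical vector.
#' @return AUC in `[0, 1]`, or `NA` if either class is absent.
#' @export
rank_auc <- function(scores, is_positive) {
  n1 <- sum(is_positive)
  n0 <- sum(!is_positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[is_positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
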