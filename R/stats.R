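# Nonparametric comparison machinery: descriptive statistics, Wilcoxon
# signed-rank and Friedman tests, and the best-classifier / top-algorithm
# selection rules used to shortlist methods across many datasets.

#' Descriptive statistics of a result vector
#'
#' @param values numeric vector (e.g. per-dataset accuracies).
#' @return list with `n`, `mean`, `sd` (sample sd, `n - 1` denominator;
#'   reported as 0 with a warning when `n = 1`), `min`, `max`.
#' @export
describe <- function(values) {
  if (length(values) < 1) stop_validation("describe needs at least one value")
  s <- if (length(values) == 1) {
    warning("sd of a single value reported as 0", call. = FALSE)
    0
  } else stats::sd(values)
  list(n = length(values), mean = mean(values), sd = s,
       min = min(values), max = max(values))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (Wilcoxon's original treatment); tied
#' absolute differences receive average ranks. `R+` and `R-` are the rank
#' sums of positive and negative differences, and the reported statistic is
#' `min(R+, R-)`. The two-sided p-value is exact (full enumeration of the
#' `2^m` sign assignments, computed by convolution over the rank
#' distribution) for `m <= 25` under `mode = "auto"`, otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param mode `"auto"` (default), `"exact"`, or `"normal"`.
#' @return a `StatTestResult` list: `test = "wilcoxon"`, `statistic`
#'   (`min(R+, R-)`), `r_plus`, `r_minus`, `n_nonzero`, `p_value`, `method`,
#'   and `degenerate` (`TRUE` when all differences are zero, in which case
#'   `p_value = 1`).
#' @export
wilcoxon_signed_rank <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) != length(y))
    stop_validation("x and y must have equal length")
  if (length(x) < 2) stop_validation("need at least 2 pairs")
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(structure(list(test = "wilcoxon", statistic = 0, r_plus = 0,
                          r_minus = 0, n_nonzero = 0L, p_value = 1,
                          method = "degenerate", degenerate = TRUE),
                     class = "StatTestResult"))
  }
  r <- rank(abs(d), ties.method = "average")
  r_plus <- sum(r[d > 0])
  r_minus <- sum(r[d < 0])
  stat <- min(r_plus, r_minus)
  if (mode == "exact" || (mode == "auto" && m <= 25)) {
    p <- wilcoxon_exact_p(r, r_plus)
    method <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (r_plus - mu - sign(r_plus - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approx"
  }
  structure(list(test = "wilcoxon", statistic = stat, r_plus = r_plus,
                 r_minus = r_minus, n_nonzero = m, p_value = p,
                 method = method, degenerate = FALSE),
            class = "StatTestResult")
}

# exact two-sided p over all 2^m equiprobable sign assignments:
# p = 2 * min(P(R+ <= obs), P(R+ >= obs)), capped at 1. Average ranks may be
# half-integers, so ranks are doubled to integers and the distribution of
# 2*R+ is built by polynomial convolution.
wilcoxon_exact_p <- function(ranks, r_plus) {
  s <- as.integer(round(2 * ranks))
  total <- sum(s)
  dist <- c(1, rep(0, total))  # dist[w + 1] = #assignments with 2*R+ == w
  for (si in s) {
    shifted <- c(rep(0, si), dist[seq_len(total + 1 - si)])
    dist <- dist + shifted
  }
  obs <- as.integer(round(2 * r_plus))
  n_total <- 2^length(s)
  p_le <- sum(dist[seq_len(obs + 1)]) / n_total
  p_ge <- sum(dist[(obs + 1):(total + 1)]) / n_total
  min(1, 2 * min(p_le, p_ge))
}

#' Friedman rank test across matched blocks
#'
#' Ranks the methods within each block (average ranks for ties) and tests
#' whether mean ranks differ, using the chi-squared form of the statistic
#' with tie correction and `df = k - 1`. When every block ranks all methods
#' identically tied (all values equal within each block) the statistic is 0
#' and `p = 1`.
#'
#' @param results numeric matrix, blocks (datasets) in rows and methods in
#'   columns; at least 2 of each.
#' @return a `StatTestResult` list: `test = "friedman"`, `statistic`
#'   (chi-squared), `df`, `p_value`, `mean_ranks`.
#' @export
friedman <- function(results) {
  results <- as.matrix(results)
  b <- nrow(results)
  k <- ncol(results)
  if (k < 2 || b < 2)
    stop_validation("friedman needs at least 2 methods and 2 blocks")
  R <- t(apply(results, 1, rank, ties.method = "average"))
  Rj <- colSums(R)
  A <- sum(R^2)
  C <- b * k * (k + 1)^2 / 4
  denom <- A - C
  stat <- if (denom <= 0) 0 else (k - 1) * sum((Rj - b * (k + 1) / 2)^2) / denom
  df <- k - 1
  p <- stats::pchisq(stat, df, lower.tail = FALSE)
  structure(list(test = "friedman", statistic = stat, df = df, p_value = p,
                 mean_ranks = Rj / b),
            class = "StatTestResult")
}

#' @export
print.StatTestResult <- function(x, ...) {
  if (x$test == "wilcoxon") {
    cat(sprintf("Wilcoxon signed-rank: R+ = %g, R- = %g, statistic = %g, p = %.4g (%s)\n",
                x$r_plus, x$r_minus, x$statistic, x$p_value, x$method))
  } else {
    cat(sprintf("Friedman: chi-squared = %.4g, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  }
  invisible(x)
}

#' Select the best classifier and top algorithms from an accuracy table
#'
#' The best classifier is the one that most often attains the per-cell
#' maximum accuracy across dataset-by-algorithm cells (ties credit every
#' tied classifier). Algorithms are then ranked by the number of datasets
#' where, using that best classifier, they attain the best accuracy (ties
#' credit all); ties in the count are broken by smaller average
#' selected-feature count, then lexicographically.
#'
#' @param results data.frame with columns `algorithm`, `dataset`,
#'   `classifier`, `accuracy`; every combination must be present.
#' @param feature_counts optional data.frame with columns `algorithm`,
#'   `dataset`, `n_features` (average selected-feature counts used for
#'   tie-breaking).
#' @param n_top number of algorithms to shortlist, default 3.
#' @return list with `best_classifier`, `classifier_counts`,
#'   `top_algorithms` (character vector of length `n_top`), and
#'   `algorithm_counts`.
#' @export
select_best <- function(results, feature_counts = NULL, n_top = 3) {
  needed <- c("algorithm", "dataset", "classifier", "accuracy")
  if (!all(needed %in% names(results)))
    stop_validation("results needs columns: %s", paste(needed, collapse = ", "))
  algs <- sort(unique(results$algorithm))
  dats <- sort(unique(results$dataset))
  clss <- sort(unique(results$classifier))
  full <- expand.grid(algorithm = algs, dataset = dats, classifier = clss,
                      stringsAsFactors = FALSE)
  key <- function(df) paste(df$algorithm, df$dataset, df$classifier)
  missing_cells <- setdiff(key(full), key(results))
  if (length(missing_cells))
    stop_validation("incomplete table; missing cells: %s",
                    paste(utils::head(missing_cells, 5), collapse = "; "))

  # classifier winning counts over dataset x algorithm cells
  cls_counts <- stats::setNames(numeric(length(clss)), clss)
  for (a in algs) for (ds in dats) {
    cell <- results[results$algorithm == a & results$dataset == ds, ]
    best <- cell$classifier[cell$accuracy == max(cell$accuracy)]
    cls_counts[best] <- cls_counts[best] + 1
  }
  best_cls <- names(cls_counts)[order(-cls_counts, names(cls_counts))][1]

  # algorithm winning counts using the best classifier
  sub <- results[results$classifier == best_cls, ]
  alg_counts <- stats::setNames(numeric(length(algs)), algs)
  for (ds in dats) {
    cell <- sub[sub$dataset == ds, ]
    best <- cell$algorithm[cell$accuracy == max(cell$accuracy)]
    alg_counts[best] <- alg_counts[best] + 1
  }
  avg_feats <- stats::setNames(rep(Inf, length(algs)), algs)
  if (!is.null(feature_counts)) {
    for (a in algs) {
      v <- feature_counts$n_features[feature_counts$algorithm == a]
      if (length(v)) avg_feats[a] <- mean(v)
    }
  }
  ord <- order(-alg_counts, avg_feats[names(alg_counts)], names(alg_counts))
  structure(list(best_classifier = best_cls, classifier_counts = cls_counts,
                 top_algorithms = names(alg_counts)[ord][seq_len(min(n_top, length(algs)))],
                 algorithm_counts = alg_counts),
            class = "SelectionSummary")
}
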