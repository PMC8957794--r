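#' Labelled sample-by-feature matrix
#'
#' The central data container: a numeric matrix with samples in rows and
#' features (genes, probes, CpG sites) in columns, one class label per
#' sample, and a logical mask marking missing entries. Missing cells are
#' stored as `NA` in `values` and `TRUE` in `missing_mask`.
#'
#' @param values numeric matrix, samples in rows, features in columns.
#'   `NA` entries are treated as missing.
#' @param labels vector of class labels, one per sample (coerced to factor).
#' @param feature_ids character vector of unique feature identifiers;
#'   defaults to `colnames(values)` or `F1..Fd`.
#' @param sample_ids character vector of unique sample identifiers;
#'   defaults to `rownames(values)` or `S1..Sn`.
#'
#' @return an object of class `FeatureMatrix`: a list with elements
#'   `values`, `labels`, `feature_ids`, `sample_ids`, `missing_mask`.
#' @export
#' @examples
#' x <- matrix(rnorm(20), nrow = 4)
#' fm <- feature_matrix(x, labels = c("a", "a", "b", "b"))
#' dim(fm$values)
feature_matrix <- function(values, labels, feature_ids = NULL, sample_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  d <- ncol(values)
  if (n < 2) stop_validation("FeatureMatrix needs at least 2 samples, got %d", n)
  if (d < 1) stop_validation("FeatureMatrix needs at least 1 feature")
  if (length(labels) != n)
    stop_validation("labels has length %d but there are %d samples", length(labels), n)
  feature_ids <- feature_ids %||% colnames(values) %||% paste0("F", seq_len(d))
  sample_ids <- sample_ids %||% rownames(values) %||% paste0("S", seq_len(n))
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != d)
    stop_validation("feature_ids has length %d but there are %d features",
                    length(feature_ids), d)
  if (length(sample_ids) != n)
    stop_validation("sample_ids has length %d but there are %d samples",
                    length(sample_ids), n)
  dup <- feature_ids[duplicated(feature_ids)]
  if (length(dup))
    stop_validation("duplicate feature identifier: '%s'", dup[1])
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup))
    stop_validation("duplicate sample identifier: '%s'", dup[1])
  dimnames(values) <- list(sample_ids, feature_ids)
  structure(
    list(
      values = values,
      labels = factor(labels),
      feature_ids = feature_ids,
      sample_ids = sample_ids,
      missing_mask = is.na(values)
    ),
    class = "FeatureMatrix"
  )
}

#' @export
print.FeatureMatrix <- function(x, ...) {
  cat(sprintf(
    "FeatureMatrix: %d samples x %d features, %d classes (%s), %d missing cells\n",
    nrow(x$values), ncol(x$values), nlevels(x$labels),
    paste(levels(x$labels), collapse = "/"), sum(x$missing_mask)
  ))
  invisible(x)
}

#' @export
dim.FeatureMatrix <- function(x) dim(x$values)

n_features <- function(m) ncol(m$values)
n_samples <- function(m) nrow(m$values)

# keep a subset of feature columns, preserving order
subset_features <- function(m, keep) {
  feature_matrix(m$values[, keep, drop = FALSE], m$labels,
                 feature_ids = m$feature_ids[keep], sample_ids = m$sample_ids)
}

assert_mask <- function(mask, d, what = "mask") {
  mask <- as.logical(mask)
  if (anyNA(mask)) stop_validation("%s contains NA", what)
  if (length(mask) != d)
    stop_validation("%s has length %d but the matrix has %d features",
                    what, length(mask), d)
  mask
}
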