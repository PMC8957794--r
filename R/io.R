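# Reading and writing delimited omics matrices and feature lists.
#
# File layout conventions:
#   * samples_in_columns (GEO series-matrix style, the default): rows are
#     features, the header line holds sample identifiers, the first field of
#     each row is the feature identifier, and one designated row holds the
#     class labels.
#   * samples_in_rows: columns are features, the header holds feature
#     identifiers, the first field of each row is the sample identifier, and
#     one designated column holds the class labels.

MISSING_TOKENS <- c("", "na", "nan", "null")

is_missing_token <- function(x) {
  tolower(trimws(x)) %in% MISSING_TOKENS
}

#' Read a labelled omics matrix from delimited text
#'
#' Parses a delimiter-separated text file with one header line of
#' identifiers into a [feature_matrix()]. Missing-value tokens (`""`, `"NA"`,
#' `"NaN"`, `"null"`, case-insensitive) are recorded in the missing mask;
#' any other non-numeric cell is a parse error reported with its file
#' coordinates.
#'
#' @param path file path.
#' @param orientation `"samples_in_columns"` (features in rows; GEO
#'   series-matrix convention; default) or `"samples_in_rows"`.
#' @param label_source name of the row (samples in columns) or column
#'   (samples in rows) holding the class labels.
#' @param delimiter field separator, default tab.
#' @return a [feature_matrix()] with samples in rows.
#' @export
read_matrix <- function(path,
                        orientation = c("samples_in_columns", "samples_in_rows"),
                        label_source = "label",
                        delimiter = "\t") {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop(sprintf("cannot read '%s': no such file", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2) stop(sprintf("'%s': need a header line and data", path))
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  header <- fields[[1]]
  body <- fields[-1]
  # strsplit drops trailing empty fields; count separators to restore them
  widths <- lengths(regmatches(lines[-1], gregexpr(delimiter, lines[-1],
                                                   fixed = TRUE))) + 1L
  if (length(unique(widths)) != 1)
    stop_validation("ragged table: line %d has %d fields, line 2 has %d",
                    which(widths != widths[1])[1] + 1, widths[widths != widths[1]][1],
                    widths[1])
  ncol_body <- widths[1]
  body <- lapply(body, function(f) c(f, rep("", ncol_body - length(f))))
  # header may or may not carry a cell above the identifier column
  if (length(header) == ncol_body) {
    col_ids <- header[-1]
  } else if (length(header) == ncol_body - 1) {
    col_ids <- header
  } else {
    stop_validation("header has %d fields but data lines have %d",
                    length(header), ncol_body)
  }
  row_ids <- vapply(body, `[`, character(1), 1L)
  cells <- t(vapply(body, function(f) f[-1L], character(ncol_body - 1L)))
  if (ncol_body == 2L) cells <- matrix(cells, ncol = 1L)

  dup <- row_ids[duplicated(row_ids)]
  if (length(dup)) stop_validation("duplicate identifier in rows: '%s'", dup[1])
  dup <- col_ids[duplicated(col_ids)]
  if (length(dup)) stop_validation("duplicate identifier in columns: '%s'", dup[1])

  if (orientation == "samples_in_columns") {
    lab_at <- match(label_source, row_ids)
    if (is.na(lab_at))
      stop_validation("label row '%s' not found", label_source)
    labels <- as.character(cells[lab_at, ])
    cells <- cells[-lab_at, , drop = FALSE]
    feature_ids <- row_ids[-lab_at]
    sample_ids <- col_ids
    values <- parse_numeric_cells(t(cells), path,
                                  line_of = function(i, j) c(which(row_ids != label_source)[j] + 1L, i + 1L))
  } else {
    lab_at <- match(label_source, col_ids)
    if (is.na(lab_at))
      stop_validation("label column '%s' not found", label_source)
    labels <- as.character(cells[, lab_at])
    cells <- cells[, -lab_at, drop = FALSE]
    feature_ids <- col_ids[-lab_at]
    sample_ids <- row_ids
    values <- parse_numeric_cells(cells, path,
                                  line_of = function(i, j) c(i + 1L, which(col_ids != label_source)[j] + 1L))
  }
  dimnames(values) <- NULL
  feature_matrix(values, labels, feature_ids = feature_ids, sample_ids = sample_ids)
}

# character matrix (samples x features) -> numeric with NA for missing tokens;
# line_of(i, j) maps a matrix cell to (file line, file field) for error text
parse_numeric_cells <- function(cells, path, line_of) {
  miss <- matrix(is_missing_token(cells), nrow = nrow(cells))
  values <- suppressWarnings(as.numeric(cells))
  bad <- which(is.na(values) & !miss)
  if (length(bad)) {
    b <- bad[1]
    i <- ((b - 1) %% nrow(cells)) + 1
    j <- ((b - 1) %/% nrow(cells)) + 1
    at <- line_of(i, j)
    stop(sprintf("'%s': non-numeric value '%s' at line %d, field %d",
                 path, cells[b], at[1], at[2]))
  }
  values <- matrix(values, nrow = nrow(cells))
  values[miss] <- NA_real_
  values
}

#' Write a FeatureMatrix to delimited text
#'
#' Writes samples in rows with a `sample_id` column, a label column, and one
#' column per feature. Values are printed with enough digits for an exact
#' double-precision round trip through [read_matrix()].
#'
#' @param m a [feature_matrix()].
#' @param path output file path.
#' @param delimiter field separator, default tab.
#' @param label_name header used for the label column, default `"label"`.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, delimiter = "\t", label_name = "label") {
  stopifnot(inherits(m, "FeatureMatrix"))
  vals <- m$values
  chr <- matrix(sprintf("%.17g", vals), nrow = nrow(vals))
  chr[is.na(vals)] <- "NA"
  header <- paste(c("sample_id", label_name, m$feature_ids), collapse = delimiter)
  rows <- vapply(seq_len(nrow(vals)), function(i) {
    paste(c(m$sample_ids[i], as.character(m$labels[i]), chr[i, ]),
          collapse = delimiter)
  }, character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Remove features that carry missing values
#'
#' Any feature with at least one missing entry in any sample is removed from
#' all samples; surviving features keep their original order and values, and
#' the labels and sample identifiers are untouched. In public omics matrices
#' such features are typically well under 0.1% of the total, so outright
#' removal is preferred over imputation.
#'
#' @param m a [feature_matrix()].
#' @return a [feature_matrix()] with an all-false missing mask.
#' @export
drop_missing_features <- function(m) {
  stopifnot(inherits(m, "FeatureMatrix"))
  affected <- colSums(m$missing_mask) > 0
  if (all(affected)) stop_validation("no features remain after removing missing values")
  if (any(affected))
    message(sprintf("drop_missing_features: removed %d of %d features (%.3f%%)",
                    sum(affected), length(affected),
                    100 * mean(affected)))
  if (!any(affected)) return(m)
  subset_features(m, !affected)
}

#' Write selected feature identifiers to a text file
#'
#' @param mask logical feature-inclusion vector.
#' @param feature_ids character vector, same length as `mask`.
#' @param path output file path; one selected identifier per line in
#'   original feature order.
#' @return `path`, invisibly.
#' @export
write_feature_list <- function(mask, feature_ids, path) {
  mask <- as.logical(mask)
  if (length(mask) != length(feature_ids))
    stop_validation("mask length %d does not match %d feature ids",
                    length(mask), length(feature_ids))
  writeLines(as.character(feature_ids[mask]), path)
  invisible(path)
}

#' Read a feature list written by [write_feature_list()]
#'
#' @param path file with one feature identifier per line.
#' @param feature_ids full feature-id vector defining the mask space.
#' @return logical mask over `feature_ids`.
#' @export
read_feature_list <- function(path, feature_ids) {
  ids <- readLines(path, warn = FALSE)
  ids <- ids[nzchar(ids)]
  unknown <- setdiff(ids, feature_ids)
  if (length(unknown))
    stop_validation("feature '%s' not present in the feature space", unknown[1])
  feature_ids %in% ids
}
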