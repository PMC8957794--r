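# Intersection/union combination of selected feature subsets.
#
# Three selection methods yield eight ensemble subsets: the four
# intersections (three pairwise plus the triple consensus) and the four
# unions. Two methods yield one of each. Intersections keep only features
# every method agreed on; unions pool everything any method selected.

#' Combine selected feature subsets by intersection and union
#'
#' @param masks named list of 2 or 3 logical masks of equal length (names
#'   default to `M1`, `M2`, `M3`).
#' @return a `CombinationSet`: list with `inputs` (the masks), `combos`
#'   (named list of combined masks; names use `&` for intersections and
#'   `|` for unions, e.g. `"SMA&PFA"`), and `empty` (named logical flag per
#'   combo; empty intersections are retained and flagged, since methods
#'   with disjoint selections produce no consensus features).
#' @export
#' @examples
#' cs <- combine_masks(list(A = c(TRUE, TRUE, FALSE), B = c(FALSE, TRUE, TRUE)))
#' names(cs$combos)
combine_masks <- function(masks) {
  if (!is.list(masks) || length(masks) < 2 || length(masks) > 3)
    stop_validation("combine_masks takes 2 or 3 masks, got %d", length(masks))
  masks <- lapply(masks, as.logical)
  d <- unique(lengths(masks))
  if (length(d) != 1)
    stop_validation("masks have differing lengths: %s",
                    paste(lengths(masks), collapse = ", "))
  nm <- names(masks) %||% paste0("M", seq_along(masks))
  nm[!nzchar(nm)] <- paste0("M", which(!nzchar(nm)))
  names(masks) <- nm
  combos <- list()
  pairs <- utils::combn(length(masks), 2, simplify = FALSE)
  for (pr in pairs)
    combos[[paste(nm[pr], collapse = "&")]] <- masks[[pr[1]]] & masks[[pr[2]]]
  if (length(masks) == 3)
    combos[[paste(nm, collapse = "&")]] <- masks[[1]] & masks[[2]] & masks[[3]]
  for (pr in pairs)
    combos[[paste(nm[pr], collapse = "|")]] <- masks[[pr[1]]] | masks[[pr[2]]]
  if (length(masks) == 3)
    combos[[paste(nm, collapse = "|")]] <- masks[[1]] | masks[[2]] | masks[[3]]
  structure(list(inputs = masks, combos = combos,
                 empty = vapply(combos, function(x) !any(x), logical(1))),
            class = "CombinationSet")
}

#' @export
print.CombinationSet <- function(x, ...) {
  cat(sprintf("CombinationSet: %d inputs over %d features\n",
              length(x$inputs), length(x$inputs[[1]])))
  for (nm in names(x$combos))
    cat(sprintf("  %-20s %6d features%s\n", nm, sum(x$combos[[nm]]),
                if (x$empty[[nm]]) "  (empty)" else ""))
  invisible(x)
}

#' Feature-selection rate of a mask
#'
#' The percentage of the original feature space that a subset retains.
#'
#' @param mask logical feature-inclusion vector.
#' @return `100 * selected / total`, in percent.
#' @export
selection_rate <- function(mask) {
  mask <- as.logical(mask)
  if (length(mask) < 1) stop_validation("mask must have length >= 1")
  100 * sum(mask) / length(mask)
}

#' Selection-rate table across datasets
#'
#' For each dataset, reports the solo selection rate of every method plus
#' the rates of all intersection and union combinations, and appends a
#' final per-column average row. Rates of empty combinations are `NA`
#' (rendered as an em dash by [format_rate_table()]); column averages are
#' taken over the non-missing cells.
#'
#' @param runs named list: dataset name -> named list of logical masks
#'   (method name -> mask), 2 or 3 methods per dataset, equal mask lengths
#'   within a dataset.
#' @return data.frame with one row per dataset plus an `"Average"` row;
#'   columns are the solo methods followed by the combination names.
#' @export
rate_table <- function(runs) {
  stopifnot(length(runs) >= 1)
  rows <- lapply(names(runs), function(ds) {
    masks <- runs[[ds]]
    if (length(unique(lengths(masks))) != 1)
      stop_validation("dataset '%s': masks have differing lengths", ds)
    cs <- combine_masks(masks)
    solo <- vapply(masks, selection_rate, numeric(1))
    combo <- vapply(names(cs$combos), function(nm) {
      if (cs$empty[[nm]]) NA_real_ else selection_rate(cs$combos[[nm]])
    }, numeric(1))
    c(solo, combo)
  })
  cols <- names(rows[[1]])
  if (!all(vapply(rows, function(r) identical(names(r), cols), logical(1))))
    stop_validation("datasets have inconsistent method sets")
  tab <- do.call(rbind, rows)
  tab <- rbind(tab, colMeans(tab, na.rm = TRUE))
  tab[is.nan(tab)] <- NA_real_
  df <- as.data.frame(tab)
  rownames(df) <- c(names(runs), "Average")
  df
}

#' Render a rate table with em dashes for missing cells
#'
#' @param tab data.frame from [rate_table()].
#' @param digits decimal places, default 4 (percentage scale).
#' @return character data.frame suitable for writing as TSV.
#' @export
format_rate_table <- function(tab, digits = 4) {
  out <- as.data.frame(lapply(tab, function(col) {
    s <- sprintf(paste0("%.", digits, "f"), col)
    s[is.na(col)] <- "—"
    s
  }), check.names = FALSE)
  rownames(out) <- rownames(tab)
  out
}
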