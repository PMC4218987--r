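#' Fragment-level (row) filters
#'
#' Applies the three data-point removal rules, all with strict
#' inequalities as stated:
#' \itemize{
#'   \item fragments *shorter than* `min_length` bp (default 150);
#'   \item fragments with zero reads in *more than* `max_zero_experiments`
#'     experiments;
#'   \item fragments on a user-supplied blacklist (stands in for the
#'     dataset-specific list of unalignable fragments).
#' }
#' `max_zero_experiments = NULL` resolves to 300 when the matrix has at
#' least 300 columns, else to 75% of the column count (the literal 300
#' is only meaningful for experiment collections of that size).
#'
#' @param matrix a `CountMatrix` of raw counts.
#' @param min_length minimum fragment length kept (bp).
#' @param max_zero_experiments maximum tolerated zero-count experiments.
#' @param blacklist character vector of fragment ids to drop.
#' @return list with `matrix` (filtered `CountMatrix`) and `report`
#'   (a `FilterReport`).
#' @export
filter_fragments <- function(matrix, min_length = 150,
                             max_zero_experiments = NULL,
                             blacklist = character()) {
  stopifnot(inherits(matrix, "CountMatrix"))
  if (is.null(max_zero_experiments)) {
    nc <- ncol(matrix$values)
    max_zero_experiments <- if (nc >= 300) 300 else ceiling(0.75 * nc)
  }
  short <- matrix$fragments$length < min_length        # strict "shorter than"
  zeros <- rowSums(matrix$values == 0) > max_zero_experiments  # strict "more than"
  black <- matrix$fragments$id %in% blacklist
  drop <- short | zeros | black
  report <- filter_report(
    axis = "fragments", input = nrow(matrix$values), removed = sum(drop),
    rules = list(
      short_fragment = matrix$fragments$id[short],
      pervasive_zero = matrix$fragments$id[zeros],
      blacklist = matrix$fragments$id[black]))
  if (all(drop)) {
    cond <- structure(
      class = c("ssr_all_removed", "error", "condition"),
      list(message = "all fragments removed by row filters",
           call = sys.call(), report = report))
    stop(cond)
  }
  message(sprintf(
    "filter_fragments: removed %d/%d rows (short %d, pervasive-zero %d, blacklist %d)",
    sum(drop), length(drop), sum(short), sum(zeros), sum(black)))
  list(matrix = subset_rows(matrix, !drop), report = report)
}

#' Experiment-level (column) filter
#'
#' Drops experiments with *fewer than* `min_reads` total raw reads
#' (strict), the depth floor below which a sorted library is too
#' shallow to contribute.
#'
#' @param matrix a `CountMatrix` of raw counts.
#' @param min_reads minimum total raw reads kept (default 100000).
#' @return list with `matrix` and `report`.
#' @export
filter_experiments <- function(matrix, min_reads = 100000) {
  stopifnot(inherits(matrix, "CountMatrix"))
  totals <- colSums(matrix$values)
  drop <- totals < min_reads  # strict "fewer than"
  report <- filter_report(
    axis = "experiments", input = ncol(matrix$values), removed = sum(drop),
    rules = list(low_depth = matrix$experiments$id[drop]))
  if (all(drop)) {
    cond <- structure(
      class = c("ssr_all_removed", "error", "condition"),
      list(message = "all experiments removed by the depth filter",
           call = sys.call(), report = report))
    stop(cond)
  }
  if (any(drop))
    message(sprintf("filter_experiments: removed %d/%d columns (%s)",
                    sum(drop), length(drop),
                    paste(matrix$experiments$id[drop], collapse = ", ")))
  list(matrix = subset_cols(matrix, !drop), report = report)
}

filter_report <- function(axis, input, removed, rules) {
  structure(list(axis = axis, input = input, removed = removed,
                 retained = input - removed,
                 rules = lapply(rules, as.character)),
            class = "FilterReport")
}

#' @export
print.FilterReport <- function(x, ...) {
  cat(sprintf("FilterReport (%s): %d input, %d removed, %d retained\n",
              x$axis, x$input, x$removed, x$retained))
  for (r in names(x$rules))
    cat(sprintf("  %-16s %d\n", r, length(x$rules[[r]])))
  invisible(x)
}

#' Serialize a filter report as JSON
#' @param report a `FilterReport`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}
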