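#' Haplotype-by-location contingency matrix
#'
#' Constructs the count matrix the spatial randomization test operates on:
#' non-negative integer counts of each haplotype (rows) at each sampling
#' location (columns). Rows or columns whose marginal total is zero are
#' dropped with a warning, because the chi-squared statistic is undefined
#' for cells with zero expectation.
#'
#' @param x a numeric matrix (or object coercible to one) of non-negative
#'   integer counts; haplotypes in rows, locations in columns.
#' @param row_labels,col_labels optional character vectors of haplotype and
#'   location names; default to the dimnames of `x` or `Hap_NN` / `Loc_NN`.
#'
#' @return an object of class `contingency_matrix`: an integer matrix with
#'   dimnames, grand total accessible via `sum()`.
#' @examples
#' m <- contingency_matrix(matrix(c(3, 1, 1, 3), 2, 2))
#' rowSums(m); colSums(m)
#' @export
contingency_matrix <- function(x, row_labels = NULL, col_labels = NULL) {
  x <- as.matrix(x)
  if (length(x) == 0L || nrow(x) == 0L || ncol(x) == 0L)
    stop("contingency matrix must have at least one row and one column")
  if (!is.numeric(x) || anyNA(x))
    stop("counts must be numeric and non-missing")
  if (any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  storage.mode(x) <- "integer"
  if (sum(x) == 0L)
    stop("contingency matrix has zero total count")

  if (is.null(row_labels))
    row_labels <- rownames(x) %||% sprintf("Hap_%02d", seq_len(nrow(x)))
  if (is.null(col_labels))
    col_labels <- colnames(x) %||% sprintf("Loc_%02d", seq_len(ncol(x)))
  stopifnot(length(row_labels) == nrow(x), length(col_labels) == ncol(x))
  dimnames(x) <- list(row_labels, col_labels)

  empty_r <- rowSums(x) == 0L
  empty_c <- colSums(x) == 0L
  if (any(empty_r) || any(empty_c)) {
    warning(sprintf(
      "dropping %d empty row(s) [%s] and %d empty column(s) [%s]",
      sum(empty_r), paste(row_labels[empty_r], collapse = ", "),
      sum(empty_c), paste(col_labels[empty_c], collapse = ", ")))
    x <- x[!empty_r, !empty_c, drop = FALSE]
  }
  structure(x, class = c("contingency_matrix", class(matrix())))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.contingency_matrix <- function(x, ...) {
  cat(sprintf("Haplotype x location counts: %d x %d, N = %d\n",
              nrow(x), ncol(x), sum(x)))
  print(unclass(x), ...)
  invisible(x)
}

#' Pool location columns into groups
#'
#' Sums the columns of a haplotype-by-location matrix within user-defined
#' groups, e.g. collapsing eleven locations into Brazil vs non-Brazil. Row
#' totals are unchanged; the grand total is preserved.
#'
#' @param x a [contingency_matrix()] (or plain count matrix).
#' @param grouping named character vector mapping every column name of `x`
#'   to its group label.
#' @return a [contingency_matrix()] with one column per group, groups in
#'   first-appearance order of `grouping`.
#' @examples
#' m <- contingency_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(NULL, c("A", "B", "C"))))
#' pool_locations(m, c(A = "west", B = "east", C = "east"))
#' @export
pool_locations <- function(x, grouping) {
  x <- if (inherits(x, "contingency_matrix")) x else contingency_matrix(x)
  missing_cols <- setdiff(colnames(x), names(grouping))
  if (length(missing_cols))
    stop("no group assigned for column(s): ",
         paste(missing_cols, collapse = ", "))
  g <- factor(grouping[colnames(x)], levels = unique(unname(grouping)))
  g <- droplevels(g)
  pooled <- t(rowsum(t(unclass(x)), g))
  contingency_matrix(pooled, row_labels = rownames(x),
                     col_labels = colnames(pooled))
}

#' Read / write a count matrix as CSV
#'
#' CSV layout: first column holds haplotype labels, header row holds
#' location labels, cells are integer counts.
#'
#' @param path file path.
#' @return `read_count_matrix()` returns a [contingency_matrix()].
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  contingency_matrix(m)
}

#' @rdname read_count_matrix
#' @param x matrix to write.
#' @export
write_count_matrix <- function(x, path) {
  df <- data.frame(haplotype = rownames(x), unclass(x),
                   check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
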