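#' Construct a categorical dataset
#'
#' Packs an N x P matrix of categorical observations into the container used
#' by all fitting functions. Categories are stored internally as dense 0-based
#' integer codes per column, with the original labels retained so that
#' round-trips through [write_categorical_matrix()] are lossless.
#'
#' @param x matrix or data.frame, rows = observations, columns = variables.
#'   Entries may be integers, characters or factors; missing values are
#'   rejected. If `n_categories` is supplied, `x` must already contain
#'   0-based integer codes.
#' @param n_categories optional integer vector of length P giving the number
#'   of categories per column. When `NULL` (default) the categories of each
#'   column are its distinct observed values, coded in sorted order (numeric
#'   sort for numeric input, lexicographic otherwise).
#' @param row_ids,column_ids optional identifier vectors; default to the
#'   dimnames of `x` or `"r<i>"` / `"V<j>"`.
#'
#' @return An object of class `catmix_data`: a list with elements `data`
#'   (N x P integer matrix of 0-based codes), `n_categories`, `levels`
#'   (per-column original labels), `row_ids`, `column_ids`.
#' @export
categorical_dataset <- function(x, n_categories = NULL,
                                row_ids = NULL, column_ids = NULL) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) stop("`x` must be a matrix or data.frame", call. = FALSE)
  if (nrow(x) < 1L || ncol(x) < 1L)
    stop("dataset must have at least one row and one column", call. = FALSE)
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing value at row %d, column %d: complete data required",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  N <- nrow(x); P <- ncol(x)
  if (is.null(row_ids))
    row_ids <- if (!is.null(rownames(x))) rownames(x) else paste0("r", seq_len(N))
  if (is.null(column_ids))
    column_ids <- if (!is.null(colnames(x))) colnames(x) else paste0("V", seq_len(P))

  if (!is.null(n_categories)) {
    n_categories <- as.integer(rep_len(n_categories, P))
    xm <- suppressWarnings(matrix(as.integer(x), N, P))
    if (anyNA(xm)) stop("non-integer entries with explicit `n_categories`", call. = FALSE)
    for (j in seq_len(P)) {
      if (any(xm[, j] < 0L | xm[, j] >= n_categories[j]))
        stop(sprintf("column %s: codes outside {0, ..., %d}",
                     column_ids[j], n_categories[j] - 1L), call. = FALSE)
    }
    levels <- lapply(n_categories, function(L) as.character(seq_len(L) - 1L))
  } else {
    codes <- matrix(0L, N, P)
    levels <- vector("list", P)
    for (j in seq_len(P)) {
      col <- x[, j]
      lev <- sort(unique(col))
      levels[[j]] <- as.character(lev)
      codes[, j] <- match(col, lev) - 1L
    }
    xm <- codes
    n_categories <- vapply(levels, length, integer(1))
  }
  if (any(n_categories < 2L))
    warning("constant column(s): ",
            paste(column_ids[n_categories < 2L], collapse = ", "),
            call. = FALSE)
  structure(
    list(data = xm, n_categories = n_categories, levels = levels,
         row_ids = as.character(row_ids), column_ids = as.character(column_ids)),
    class = "catmix_data")
}

#' @export
print.catmix_data <- function(x, ...) {
  cat(sprintf("Categorical dataset: %d observations x %d variables\n",
              nrow(x$data), ncol(x$data)))
  cat("Categories per variable: ",
      paste(range(x$n_categories), collapse = "-"), "\n")
  invisible(x)
}

#' @export
dim.catmix_data <- function(x) dim(x$data)

#' Read a categorical data matrix from delimited text
#'
#' @param path CSV or TSV file; the separator is taken from the file
#'   extension unless `sep` is given.
#' @param header logical; does the first line name the columns?
#' @param row_ids_col optional column (index or name) holding row identifiers.
#' @param sep field separator; default `","` for `.csv`, `"\t"` otherwise.
#' @param ... passed to [categorical_dataset()] (e.g. `n_categories`).
#' @return A `catmix_data` object.
#' @export
read_categorical_matrix <- function(path, header = TRUE, row_ids_col = NULL,
                                    sep = NULL, ...) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = header, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  rid <- NULL
  if (!is.null(row_ids_col)) {
    idx <- if (is.character(row_ids_col)) match(row_ids_col, names(df)) else as.integer(row_ids_col)
    if (is.na(idx) || idx < 1L || idx > ncol(df))
      stop("row_ids_col not found: ", row_ids_col, call. = FALSE)
    rid <- df[[idx]]
    df <- df[, -idx, drop = FALSE]
  }
  if (nrow(df) < 2L)
    stop("fewer than two data rows in ", path, call. = FALSE)
  if (anyNA(df)) {
    bad <- which(is.na(as.matrix(df)), arr.ind = TRUE)[1L, ]
    stop(sprintf("empty cell at row %d, column '%s' of %s",
                 bad[1L], names(df)[bad[2L]], path), call. = FALSE)
  }
  m <- as.matrix(df)
  # keep numeric columns numeric so category order is numeric, not lexicographic
  num <- !anyNA(suppressWarnings(as.numeric(m)))
  if (num) m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  categorical_dataset(m, row_ids = rid, column_ids = colnames(df), ...)
}

#' Write a categorical dataset back to delimited text
#'
#' Inverse of [read_categorical_matrix()]: original category labels are
#' restored from the stored per-column mappings.
#'
#' @param data a `catmix_data` object.
#' @param path output file; `.csv` gives comma separation, anything else tab.
#' @param row_ids logical; write the row identifiers as a leading column?
#' @export
write_categorical_matrix <- function(data, path, row_ids = FALSE) {
  stopifnot(inherits(data, "catmix_data"))
  P <- ncol(data$data)
  out <- vapply(seq_len(P),
                function(j) data$levels[[j]][data$data[, j] + 1L],
                character(nrow(data$data)))
  out <- matrix(out, nrow = nrow(data$data))
  colnames(out) <- data$column_ids
  df <- as.data.frame(out, check.names = FALSE)
  if (row_ids) df <- cbind(id = data$row_ids, df)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
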