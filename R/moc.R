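#' Build a Matrix of Clusters from several partitions
#'
#' For integrative (cluster-of-clusters) analysis: given M partitions of the
#' same N samples — typically one clustering per 'omics platform — stacks one
#' binary row per (dataset, cluster) pair, with entry 1 iff the sample
#' belongs to that cluster in that dataset. Within each dataset's row block
#' every sample has exactly one 1. The transposed (N x K) matrix is a valid
#' binary categorical dataset and can be clustered directly.
#'
#' @param partitions list of M vectors of common length N (named elements
#'   give the dataset labels). If the vectors carry names they are treated
#'   as sample IDs and must agree across partitions.
#' @return Object of class `catmix_moc`: list with `moc` (K x N binary
#'   matrix, K = sum of per-dataset cluster counts), `source_labels`
#'   (data.frame with `dataset` and `cluster` per row), `sample_ids`.
#' @export
build_matrix_of_clusters <- function(partitions) {
  if (!is.list(partitions) || length(partitions) < 1L)
    stop("`partitions` must be a non-empty list", call. = FALSE)
  N <- length(partitions[[1L]])
  if (any(vapply(partitions, length, integer(1)) != N))
    stop("all partitions must cover the same samples", call. = FALSE)
  ids <- names(partitions[[1L]])
  if (!is.null(ids)) {
    for (m in seq_along(partitions)) {
      nm <- names(partitions[[m]])
      if (is.null(nm) || !identical(sort(nm), sort(ids)))
        stop("sample IDs differ across partitions", call. = FALSE)
      partitions[[m]] <- partitions[[m]][ids]  # align to first partition
    }
  }
  dsn <- names(partitions)
  if (is.null(dsn)) dsn <- paste0("dataset", seq_along(partitions))
  rows <- list(); src <- list()
  for (m in seq_along(partitions)) {
    z <- partitions[[m]]
    for (v in unique(z)) {
      rows[[length(rows) + 1L]] <- as.integer(z == v)
      src[[length(src) + 1L]] <- data.frame(dataset = dsn[m],
                                            cluster = as.character(v))
    }
  }
  moc <- do.call(rbind, rows)
  src <- do.call(rbind, src)
  rownames(moc) <- paste(src$dataset, src$cluster, sep = ".")
  if (!is.null(ids)) colnames(moc) <- ids
  structure(list(moc = moc, source_labels = src, sample_ids = ids),
            class = "catmix_moc")
}

#' @export
print.catmix_moc <- function(x, ...) {
  cat(sprintf("Matrix of Clusters: %d cluster rows x %d samples (%d datasets)\n",
              nrow(x$moc), ncol(x$moc), length(unique(x$source_labels$dataset))))
  invisible(x)
}

#' Convert a Matrix of Clusters to a binary categorical dataset
#'
#' Transposes the K x N matrix to N x K so each (dataset, cluster) indicator
#' becomes a binary variable, ready for [catmix_fit()] or
#' [run_avg_pipeline()].
#'
#' @param moc a `catmix_moc` object.
#' @return A `catmix_data` object.
#' @export
moc_as_dataset <- function(moc) {
  stopifnot(inherits(moc, "catmix_moc"))
  categorical_dataset(t(moc$moc), n_categories = 2L,
                      row_ids = moc$sample_ids,
                      column_ids = rownames(moc$moc))
}
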