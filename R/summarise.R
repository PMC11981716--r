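#' Co-clustering matrix of an ensemble of partitions
#'
#' For M partitions of the same N observations, entry (i, j) is the fraction
#' of partitions in which i and j share a cluster — the variational analogue
#' of the posterior similarity matrix used in post-processing MCMC output.
#' Only co-membership matters; label values are irrelevant.
#'
#' @param partitions list of M integer/character vectors of common length N,
#'   or an M x N matrix (one partition per row).
#' @return Object of class `catmix_ccm`: list with `P` (N x N symmetric
#'   matrix, unit diagonal, entries multiples of 1/M), `M`, `N`.
#' @export
coclustering_matrix <- function(partitions) {
  if (is.matrix(partitions))
    partitions <- lapply(seq_len(nrow(partitions)), function(m) partitions[m, ])
  M <- length(partitions)
  if (M < 1L) stop("at least one partition required", call. = FALSE)
  N <- length(partitions[[1L]])
  lens <- vapply(partitions, length, integer(1))
  if (any(lens != N))
    stop("all partitions must have the same length", call. = FALSE)
  acc <- matrix(0, N, N)
  for (z in partitions) {
    f <- as.integer(factor(z))
    Z <- matrix(0, N, max(f))
    Z[cbind(seq_len(N), f)] <- 1
    acc <- acc + tcrossprod(Z)
  }
  structure(list(P = acc / M, M = M, N = N), class = "catmix_ccm")
}

#' @export
print.catmix_ccm <- function(x, ...) {
  cat(sprintf("Co-clustering matrix: %d observations, %d partitions\n",
              x$N, x$M))
  invisible(x)
}

.consensus_result <- function(partition, method, score = NA_real_) {
  partition <- as.integer(factor(partition, levels = unique(partition)))
  structure(list(partition = partition, method = method, score = score,
                 n_clusters = length(unique(partition))),
            class = "catmix_consensus")
}

#' @export
print.catmix_consensus <- function(x, ...) {
  cat(sprintf("Consensus partition (%s): %d clusters over %d observations\n",
              x$method, x$n_clusters, length(x$partition)))
  if (is.finite(x$score))
    cat(sprintf("  expected-VoI bound: %.4f bits\n", x$score))
  invisible(x)
}

#' Medvedovic consensus partition
#'
#' Treats one minus the co-clustering frequency as a distance and applies
#' complete-linkage agglomerative clustering, cutting the dendrogram just
#' below height 1 (default 0.99) so that any pair of observations that ever
#' co-clusters can end up grouped.
#'
#' @param ccm a `catmix_ccm` object.
#' @param cut_height dendrogram cut height on the 1 - P distance scale.
#' @return A `catmix_consensus` object (no score is attached).
#' @export
medvedovic_summary <- function(ccm, cut_height = 0.99) {
  stopifnot(inherits(ccm, "catmix_ccm"))
  hc <- stats::hclust(stats::as.dist(1 - ccm$P), method = "complete")
  .consensus_result(stats::cutree(hc, h = cut_height), "medvedovic")
}

#' Lower bound on the posterior-expected variation of information
#'
#' Scores a candidate partition against a co-clustering matrix using the
#' Jensen lower bound on the expected variation of information (base-2
#' logarithms): the average over observations of
#' `log2 |C_i| + log2 sum_j P_ij - 2 log2 sum_{j in C_i} P_ij`,
#' where `C_i` is the candidate cluster containing observation i. Lower is
#' better; the bound is exactly 0 when the matrix is the binary
#' co-membership matrix of the candidate itself.
#'
#' @param partition integer/character vector of length N.
#' @param ccm a `catmix_ccm` object.
#' @return A finite scalar (bits).
#' @export
expected_voi_score <- function(partition, ccm) {
  stopifnot(inherits(ccm, "catmix_ccm"))
  N <- ccm$N
  if (length(partition) != N)
    stop("partition length does not match the co-clustering matrix", call. = FALSE)
  f <- as.integer(factor(partition))
  sizes <- tabulate(f)
  within <- rowsum(ccm$P, f)                 # k x N: column sums of P by cluster
  own <- within[cbind(f, seq_len(N))]        # sum_{j in C_i} P_ij  (>= P_ii = 1)
  val <- mean(log2(sizes[f]) + log2(rowSums(ccm$P)) - 2 * log2(own))
  if (!is.finite(val)) stop("non-finite expected-VoI score", call. = FALSE)
  val
}

#' Minimum expected-VoI consensus partition
#'
#' Builds the agglomerative dendrogram on the 1 - P distance with the given
#' linkage; the candidate partitions are its cuts into 1..`max_k` clusters
#' and the cut minimising [expected_voi_score()] is returned (ties go to the
#' smaller number of clusters).
#'
#' @param ccm a `catmix_ccm` object.
#' @param linkage `"complete"` (default) or `"average"`.
#' @param max_k largest number of clusters considered.
#' @return A `catmix_consensus` object carrying the winning score.
#' @export
minvi_summary <- function(ccm, linkage = c("complete", "average"),
                          max_k = NULL) {
  stopifnot(inherits(ccm, "catmix_ccm"))
  linkage <- match.arg(linkage)
  if (is.null(max_k)) max_k <- ccm$N
  max_k <- min(as.integer(max_k), ccm$N)
  if (max_k < 1L) stop("`max_k` must be at least 1", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(1 - ccm$P), method = linkage)
  cuts <- stats::cutree(hc, k = seq_len(max_k))
  cuts <- matrix(cuts, nrow = ccm$N)         # one column per k
  scores <- apply(cuts, 2L, expected_voi_score, ccm = ccm)
  best <- which.min(scores)                  # first minimum = smallest k
  .consensus_result(cuts[, best], paste0("voi_", linkage), scores[best])
}

#' Consensus selected-variable set across runs
#'
#' Computes, for each variable, the proportion of runs that selected it and
#' thresholds the proportions (strictly) at `tau`.
#'
#' @param selection_runs M x P logical (or 0/1) matrix, one row per run.
#' @param tau threshold in (0, 1); default 0.95.
#' @return Object of class `catmix_selection`: `proportions`, `tau`,
#'   `selected` (`proportions > tau`).
#' @export
summarize_selection <- function(selection_runs, tau = 0.95) {
  selection_runs <- as.matrix(selection_runs)
  if (nrow(selection_runs) < 1L)
    stop("at least one run required", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0 || tau >= 1)
    stop("`tau` must lie strictly between 0 and 1", call. = FALSE)
  props <- colMeans(selection_runs != 0)
  structure(list(proportions = props, tau = tau, selected = props > tau),
            class = "catmix_selection")
}

#' @export
print.catmix_selection <- function(x, ...) {
  cat(sprintf("Selection summary: %d / %d variables above tau = %g\n",
              sum(x$selected), length(x$selected), x$tau))
  invisible(x)
}
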