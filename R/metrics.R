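#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement computed from the contingency table of the two
#' labellings: 1 for identical partitions (up to relabelling), approximately
#' 0 for independent ones. Degenerate cases where the chance correction has
#' zero denominator (both partitions trivial in the same way) return 1.
#'
#' @param a,b label vectors of equal length.
#' @return Scalar in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions must have equal length", call. = FALSE)
  n <- length(a)
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  expected <- sa * sb / choose(n, 2)
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1)
  (sij - expected) / denom
}

#' F1 score of a selected-variable set against the truth
#'
#' Harmonic mean of precision and recall of the predicted positive set;
#' returns 0 when nothing is predicted positive.
#'
#' @param selected,truth logical vectors of equal length; `truth` must
#'   contain at least one positive.
#' @return Scalar in \[0, 1\].
#' @export
selection_f1 <- function(selected, truth) {
  if (length(selected) != length(truth))
    stop("vectors must have equal length", call. = FALSE)
  selected <- as.logical(selected); truth <- as.logical(truth)
  if (!any(truth)) stop("`truth` must contain at least one positive", call. = FALSE)
  tp <- sum(selected & truth)
  fp <- sum(selected & !truth)
  fn <- sum(!selected & truth)
  if (tp + fp == 0L) return(0)
  2 * tp / (2 * tp + fp + fn)
}
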