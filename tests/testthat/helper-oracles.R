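# Independent brute-force oracles used to check the vectorised implementations.

# all set partitions of n elements as restricted-growth label vectors
all_partitions <- function(n) {
  res <- list()
  rec <- function(rgs, mx) {
    if (length(rgs) == n) {
      res[[length(res) + 1L]] <<- rgs
      return(invisible(NULL))
    }
    for (v in seq_len(mx + 1L)) rec(c(rgs, v), max(mx, v))
  }
  rec(1L, 1L)
  res
}

# adjusted Rand index by explicit pair counting (no contingency table)
ari_pair_counting <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa) n10 <- n10 + 1
    else if (sb) n01 <- n01 + 1
  }
  tot <- choose(n, 2)
  t1 <- n11 + n10; t2 <- n11 + n01
  expected <- t1 * t2 / tot
  denom <- (t1 + t2) / 2 - expected
  if (denom == 0) return(1)
  (n11 - expected) / denom
}

# expected-VoI lower bound by explicit double loop over observations
evoi_loops <- function(part, P) {
  N <- length(part)
  tot <- 0
  for (i in seq_len(N)) {
    s1 <- 0; s2 <- 0; s3 <- 0
    for (j in seq_len(N)) {
      same <- part[i] == part[j]
      s1 <- s1 + same
      s2 <- s2 + P[i, j]
      if (same) s3 <- s3 + P[i, j]
    }
    tot <- tot + log2(s1) + log2(s2) - 2 * log2(s3)
  }
  tot / N
}

# exact log evidence of the Dirichlet-categorical model with one component:
# sum over variables of log B(eps + counts) - log B(eps)
dirichlet_categorical_evidence <- function(X, L, eps) {
  lmb <- function(a) sum(lgamma(a)) - lgamma(sum(a))
  sum(vapply(seq_len(ncol(X)), function(j) {
    cnt <- tabulate(X[, j] + 1L, nbins = L[j])
    e <- rep(eps[j], L[j])
    lmb(e + cnt) - lmb(e)
  }, 0))
}

# small random categorical dataset (0-based codes, explicit category counts)
random_dataset <- function(N, P, L = 2L, seed = 1L) {
  set.seed(seed)
  X <- matrix(sample.int(L, N * P, replace = TRUE) - 1L, N, P)
  categorical_dataset(X, n_categories = rep(L, P))
}
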