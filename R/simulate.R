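#' Describe a synthetic clustering scenario
#'
#' Encodes the generating conditions for cluster-structured categorical data
#' with optional cluster-independent "noise" variables: N observations split
#' over `K_true` clusters whose sizes are drawn within `cluster_sizes`, P
#' variables of which a fraction `relevant_fraction` carries cluster signal.
#' For binary data each relevant (cluster, variable) pair gets an
#' independent Beta(1, 5) success probability — sparse probabilities varying
#' across clusters — while each noise variable gets a single Beta(1, 5)
#' probability shared by every cluster.
#'
#' @param N number of observations.
#' @param P number of variables.
#' @param K_true number of planted clusters.
#' @param cluster_sizes either a length-2 integer range (min, max) for the
#'   per-cluster sizes, or an explicit length-`K_true` vector of proportions
#'   summing to 1.
#' @param relevant_fraction fraction of variables carrying cluster structure,
#'   in (0, 1].
#' @param n_categories number of categories per variable (constant), >= 2.
#' @param seed integer RNG seed.
#' @return Object of class `catmix_design`.
#' @export
simulation_design <- function(N = 1000L, P = 100L, K_true = 10L,
                              cluster_sizes = c(50L, 200L),
                              relevant_fraction = 1, n_categories = 2L,
                              seed = 1L) {
  N <- as.integer(N); P <- as.integer(P); K_true <- as.integer(K_true)
  n_categories <- as.integer(n_categories)
  if (n_categories < 2L) stop("`n_categories` must be >= 2", call. = FALSE)
  if (relevant_fraction <= 0 || relevant_fraction > 1)
    stop("`relevant_fraction` must be in (0, 1]", call. = FALSE)
  if (length(cluster_sizes) == 2L && is.numeric(cluster_sizes) &&
      all(cluster_sizes == round(cluster_sizes))) {
    lo <- cluster_sizes[1L]; hi <- cluster_sizes[2L]
    if (K_true * lo > N || K_true * hi < N)
      stop(sprintf("size range [%d, %d] infeasible for N = %d, K = %d",
                   lo, hi, N, K_true), call. = FALSE)
  } else if (length(cluster_sizes) == K_true) {
    if (abs(sum(cluster_sizes) - 1) > 1e-8)
      stop("explicit cluster proportions must sum to 1", call. = FALSE)
  } else stop("`cluster_sizes` must be a (min, max) range or K_true proportions",
              call. = FALSE)
  structure(list(N = N, P = P, K_true = K_true,
                 cluster_sizes = cluster_sizes,
                 relevant_fraction = relevant_fraction,
                 n_categories = n_categories, seed = as.integer(seed)),
            class = "catmix_design")
}

# largest-remainder rounding of positive targets to integers summing to N,
# keeping every cluster non-empty
.round_to_sum <- function(target, N) {
  base <- floor(target)
  short <- N - sum(base)
  if (short > 0) {
    extra <- order(target - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  base <- as.integer(base)
  while (any(base == 0L)) {
    base[which.max(base)] <- base[which.max(base)] - 1L
    base[which.min(base)] <- base[which.min(base)] + 1L
  }
  base
}

#' Generate a synthetic categorical dataset with planted clusters
#'
#' Cluster sizes are drawn uniformly within the design's range and rescaled
#' to sum to N by largest-remainder rounding (explicit proportions are used
#' as given). Entries are sampled independently given the per-cluster
#' category probabilities; noise variables share one probability vector
#' across all clusters, so they carry no information about cluster
#' membership. The same design (including its seed) reproduces the dataset
#' exactly.
#'
#' @param design a `catmix_design` object.
#' @return Object of class `catmix_simdata`: list with `dataset`
#'   (`catmix_data`), `true_labels`, `relevant` (logical P-vector),
#'   `generating_probs` (K_true x P x L array), `sizes`, `design`.
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "catmix_design"))
  set.seed(design$seed)
  N <- design$N; P <- design$P; K <- design$K_true; L <- design$n_categories
  if (length(design$cluster_sizes) == 2L) {
    draw <- stats::runif(K, design$cluster_sizes[1L], design$cluster_sizes[2L] + 1)
    sizes <- .round_to_sum(floor(draw) / sum(floor(draw)) * N, N)
  } else {
    sizes <- .round_to_sum(design$cluster_sizes * N, N)
  }
  labels <- rep(seq_len(K), sizes)
  n_rel <- max(1L, round(design$relevant_fraction * P))
  relevant <- c(rep(TRUE, n_rel), rep(FALSE, P - n_rel))

  probs <- array(NA_real_, c(K, P, L))
  for (j in seq_len(P)) {
    if (L == 2L) {
      p1 <- if (relevant[j]) stats::rbeta(K, 1, 5)
            else rep(stats::rbeta(1, 1, 5), K)
      probs[, j, ] <- cbind(1 - p1, p1)      # category 1 is the "success"
    } else {
      g <- if (relevant[j]) matrix(stats::rexp(K * L), K, L)
           else matrix(rep(stats::rexp(L), each = K), K, L)
      probs[, j, ] <- g / rowSums(g)         # symmetric Dirichlet(1)
    }
  }
  X <- matrix(0L, N, P)
  for (j in seq_len(P)) {
    cp <- t(apply(probs[, j, , drop = FALSE], 1L, cumsum))  # K x L
    u <- stats::runif(N)
    X[, j] <- rowSums(u > cp[labels, , drop = FALSE])       # 0-based category
  }
  structure(
    list(dataset = categorical_dataset(X, n_categories = rep(L, P)),
         true_labels = labels, relevant = relevant,
         generating_probs = probs, sizes = sizes, design = design),
    class = "catmix_simdata")
}

#' @export
print.catmix_simdata <- function(x, ...) {
  d <- x$design
  cat(sprintf(
    "Synthetic categorical data: N = %d, P = %d (%d relevant), K_true = %d, L = %d\n",
    d$N, d$P, sum(x$relevant), d$K_true, d$n_categories))
  invisible(x)
}

#' Run a replicated multi-start clustering experiment
#'
#' For each of `n_datasets` datasets drawn from `design`, fits the mixture
#' `M` times with different random initialisations, then builds consensus
#' partitions from growing sub-ensembles and, when variable selection is on,
#' consensus selected-variable sets at each threshold in `tau_list`.
#' Dataset d uses seed `base_seed + 10000 * d`; run m on dataset d uses seed
#' `base_seed + 10000 * d + m`, so runs are reproducible independently of
#' execution order. A failed fit is dropped with a warning.
#'
#' @param design a `catmix_design` object (its own seed is ignored here).
#' @param K_init number of mixture components to initialise with.
#' @param M runs per dataset (default 25).
#' @param methods consensus methods, subset of
#'   `c("medvedovic", "voi_average", "voi_complete")`.
#' @param tau_list selection thresholds (used when `variable_selection`).
#' @param n_datasets number of independent datasets.
#' @param base_seed integer base seed.
#' @param ensemble_sizes sub-ensemble sizes to summarise; default just `M`.
#' @param alpha0,a mixture hyperparameters (see [catmix_hyper()]).
#' @param variable_selection logical; default on iff the design contains
#'   noise variables.
#' @param n_workers parallel workers for the fits (forked; results are
#'   identical to serial execution because every run seeds itself).
#' @param tol,max_iter convergence controls passed to [catmix_fit()].
#' @return A long-format data.frame with columns `dataset`, `unit`
#'   (`"run"`, `"consensus"` or `"selection"`), `method`, `n_runs`, `run`,
#'   `tau`, `metric`, `value`. Per-run rows carry `ari` and `n_nonempty`;
#'   consensus rows `ari` and `n_clusters`; selection rows `f1` and
#'   `n_selected`.
#' @export
run_experiment <- function(design, K_init, M = 25L,
                           methods = "voi_complete",
                           tau_list = c(0.5, 0.95),
                           n_datasets = 1L, base_seed = 1L,
                           ensemble_sizes = NULL,
                           alpha0 = 0.01, a = 2,
                           variable_selection = design$relevant_fraction < 1,
                           n_workers = 1L, tol = 5e-8, max_iter = 2000L) {
  stopifnot(inherits(design, "catmix_design"), M >= 1L, n_datasets >= 1L)
  methods <- match.arg(methods,
                       c("medvedovic", "voi_average", "voi_complete"),
                       several.ok = TRUE)
  if (is.null(ensemble_sizes)) ensemble_sizes <- M
  ensemble_sizes <- sort(unique(pmin(as.integer(ensemble_sizes), M)))
  hyper <- catmix_hyper(K_init, alpha0 = alpha0, a = a,
                        variable_selection = variable_selection)
  rows <- list()
  add <- function(...) rows[[length(rows) + 1L]] <<- data.frame(...)

  for (d in seq_len(n_datasets)) {
    dsgn <- design
    dsgn$seed <- base_seed + 10000L * d
    sim <- generate_dataset(dsgn)
    seeds <- base_seed + 10000L * d + seq_len(M)
    fits <- .run_fits(sim$dataset, hyper, seeds, n_workers, tol, max_iter)
    ok <- !vapply(fits, is.null, logical(1))
    if (!all(ok))
      warning(sprintf("dataset %d: %d of %d runs failed and were excluded",
                      d, sum(!ok), M), call. = FALSE)
    fits <- fits[ok]
    if (length(fits) == 0L) next

    for (m in seq_along(fits)) {
      f <- fits[[m]]
      ari <- adjusted_rand_index(f$map_partition, sim$true_labels)
      add(dataset = d, unit = "run", method = NA, n_runs = NA, run = m,
          tau = NA, metric = "ari", value = ari)
      add(dataset = d, unit = "run", method = NA, n_runs = NA, run = m,
          tau = NA, metric = "n_nonempty", value = f$n_nonempty)
    }
    parts <- lapply(fits, `[[`, "map_partition")
    for (s in ensemble_sizes[ensemble_sizes <= length(fits)]) {
      ccm <- coclustering_matrix(parts[seq_len(s)])
      for (meth in methods) {
        cons <- .consensus_by_name(ccm, meth, max_k = K_init)
        add(dataset = d, unit = "consensus", method = meth, n_runs = s,
            run = NA, tau = NA, metric = "ari",
            value = adjusted_rand_index(cons$partition, sim$true_labels))
        add(dataset = d, unit = "consensus", method = meth, n_runs = s,
            run = NA, tau = NA, metric = "n_clusters", value = cons$n_clusters)
      }
      if (variable_selection) {
        selmat <- do.call(rbind, lapply(fits[seq_len(s)], `[[`, "selected"))
        for (tau in tau_list) {
          ss <- summarize_selection(selmat, tau)
          add(dataset = d, unit = "selection", method = NA, n_runs = s,
              run = NA, tau = tau, metric = "f1",
              value = selection_f1(ss$selected, sim$relevant))
          add(dataset = d, unit = "selection", method = NA, n_runs = s,
              run = NA, tau = tau, metric = "n_selected",
              value = sum(ss$selected))
        }
      }
    }
  }
  do.call(rbind, rows)
}

.consensus_by_name <- function(ccm, method, max_k) {
  switch(method,
         medvedovic   = medvedovic_summary(ccm),
         voi_average  = minvi_summary(ccm, "average", max_k),
         voi_complete = minvi_summary(ccm, "complete", max_k),
         stop("unknown consensus method: ", method, call. = FALSE))
}

.run_fits <- function(dataset, hyper, seeds, n_workers, tol, max_iter) {
  one <- function(s) tryCatch(
    suppressWarnings(catmix_fit(dataset, hyper, seed = s,
                                tol = tol, max_iter = max_iter)),
    error = function(e) NULL)
  if (n_workers > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(seeds, one, mc.cores = n_workers)
  else lapply(seeds, one)
}
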