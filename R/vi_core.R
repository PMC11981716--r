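#' Hyperparameters for the variational categorical mixture
#'
#' The mixture is fitted in the overfitted regime: `K` is set above the number
#' of clusters expected and the symmetric Dirichlet weight prior uses a
#' concentration `alpha0 < 1`, so superfluous components are emptied during
#' inference and the number of non-empty clusters estimates the true number
#' of clusters.
#'
#' @param K initial / maximum number of mixture components (at least 2).
#' @param alpha0 symmetric Dirichlet concentration for the mixture weights;
#'   values below 1 (default 0.01) favour emptying of unused components.
#' @param a shape of the symmetric Beta(a, a) hyperprior on each variable's
#'   prior inclusion probability; default 2.
#' @param epsilon per-variable symmetric Dirichlet concentration for the
#'   cluster-specific category probabilities. `NULL` (default) resolves to
#'   `1 / L_j` per variable, expressing no prior preference among categories.
#' @param variable_selection logical; switch the feature-saliency layer on?
#'   When off, every variable is always included (`c_j = 1`).
#' @return An object of class `catmix_hyper`.
#' @export
catmix_hyper <- function(K, alpha0 = 0.01, a = 2, epsilon = NULL,
                         variable_selection = FALSE) {
  K <- as.integer(K)
  if (length(K) != 1L || is.na(K) || K < 1L)
    stop("`K` must be a positive integer", call. = FALSE)
  if (!is.numeric(alpha0) || alpha0 <= 0)
    stop("`alpha0` must be positive", call. = FALSE)
  if (!is.numeric(a) || a <= 0)
    stop("`a` must be positive", call. = FALSE)
  if (!is.null(epsilon) && any(epsilon <= 0))
    stop("`epsilon` must be positive", call. = FALSE)
  structure(list(K = K, alpha0 = alpha0, a = a, epsilon = epsilon,
                 variable_selection = isTRUE(variable_selection)),
            class = "catmix_hyper")
}

.resolve_epsilon <- function(hyper, data) {
  if (is.null(hyper$epsilon)) 1 / data$n_categories
  else rep_len(hyper$epsilon, ncol(data$data))
}

#' Null-model category probabilities
#'
#' Estimates, for every variable, the category probabilities under the
#' assumption of no clustering structure. These are smoothed empirical
#' frequencies — the posterior mean under the per-variable symmetric
#' Dirichlet(epsilon_j) prior — precomputed once and held fixed during
#' fitting; de-selected variables are modelled by these probabilities.
#'
#' @param data a `catmix_data` object.
#' @param epsilon per-variable positive smoothing constants (recycled);
#'   default `1 / L_j`.
#' @return An object of class `catmix_null` with elements `phi0` (list of
#'   per-variable probability vectors) and `log_phi0`.
#' @export
estimate_null_params <- function(data, epsilon = NULL) {
  stopifnot(inherits(data, "catmix_data"))
  P <- ncol(data$data); N <- nrow(data$data)
  epsilon <- if (is.null(epsilon)) 1 / data$n_categories else rep_len(epsilon, P)
  if (any(epsilon <= 0)) stop("`epsilon` must be positive", call. = FALSE)
  phi0 <- vector("list", P)
  for (j in seq_len(P)) {
    L <- data$n_categories[j]
    cnt <- tabulate(data$data[, j] + 1L, nbins = L)
    phi0[[j]] <- (cnt + epsilon[j]) / (N + L * epsilon[j])
  }
  names(phi0) <- data$column_ids
  structure(list(phi0 = phi0, log_phi0 = lapply(phi0, log)),
            class = "catmix_null")
}

# Precomputed per-fit quantities: category indicator matrices, the null model
# in matrix layout, and the per-variable constant U_j = sum_n log phi0_{j,x_nj}
# entering both the selection update and the ELBO.
.catmix_model <- function(data, hyper, null = NULL) {
  X <- data$data
  N <- nrow(X); P <- ncol(X)
  L <- data$n_categories
  Lmax <- max(L)
  eps <- .resolve_epsilon(hyper, data)
  if (is.null(null)) null <- estimate_null_params(data, eps)
  ind <- vector("list", Lmax)        # N x P indicator of x_nj == l
  logphi0 <- matrix(0, P, Lmax)      # invalid cells stay 0 and are masked out
  for (l in seq_len(Lmax)) {
    ind[[l]] <- (X == (l - 1L)) * 1
    v <- L >= l
    logphi0[v, l] <- vapply(which(v), function(j) null$log_phi0[[j]][l], 0)
  }
  colmask <- lapply(seq_len(Lmax), function(l) L >= l)  # valid columns per level
  U <- numeric(P)
  for (l in seq_len(Lmax)) U <- U + colSums(ind[[l]]) * logphi0[, l]
  list(data = data, hyper = hyper, null = null, N = N, P = P, L = L,
       Lmax = Lmax, eps = eps, ind = ind, logphi0 = logphi0,
       colmask = colmask, U = U)
}

# one conjugate parameter pass given responsibilities and inclusion
# probabilities: q(pi), q(Phi), q(delta)
.update_params <- function(state, model) {
  hyper <- model$hyper
  K <- ncol(state$resp)
  state$alpha <- hyper$alpha0 + colSums(state$resp)
  beta <- vector("list", model$Lmax)
  cmat <- matrix(state$c, K, model$P, byrow = TRUE)
  for (l in seq_len(model$Lmax)) {
    b <- crossprod(state$resp, model$ind[[l]]) * cmat
    b <- sweep(b, 2L, model$eps, "+")
    b[, !model$colmask[[l]]] <- 0
    beta[[l]] <- b
  }
  state$beta <- beta
  state$beta_c <- state$c  # inclusion probabilities the counts were weighted by
  if (hyper$variable_selection)
    state$delta <- cbind(hyper$a + state$c, hyper$a + 1 - state$c)
  state
}

.elog_phi <- function(state, model) {
  betasum <- Reduce(`+`, state$beta)
  dgs <- digamma(betasum)
  lapply(seq_len(model$Lmax), function(l) {
    e <- digamma(pmax(state$beta[[l]], 1e-300)) - dgs
    e[, !model$colmask[[l]]] <- 0
    e
  })
}

#' Build a variational state from given responsibilities
#'
#' Low-level constructor: takes an explicit N x K responsibility matrix (and
#' optional inclusion probabilities) and completes the remaining factors with
#' one conjugate parameter pass. Used for deterministic initialisation in
#' tests and for degenerate cases such as K = 1.
#'
#' @param data a `catmix_data` object.
#' @param hyper a `catmix_hyper` object.
#' @param resp N x K matrix with non-negative rows summing to 1.
#' @param c_init inclusion probabilities, default all 1.
#' @return An object of class `catmix_state`.
#' @export
state_from_responsibilities <- function(data, hyper, resp, c_init = NULL) {
  stopifnot(inherits(data, "catmix_data"), inherits(hyper, "catmix_hyper"))
  resp <- as.matrix(resp)
  if (nrow(resp) != nrow(data$data))
    stop("`resp` must have one row per observation", call. = FALSE)
  if (any(abs(rowSums(resp) - 1) > 1e-8) || any(resp < 0))
    stop("rows of `resp` must be probability vectors", call. = FALSE)
  P <- ncol(data$data)
  cj <- if (is.null(c_init)) rep(1, P) else rep_len(cj_clip(c_init), P)
  state <- structure(
    list(resp = resp, alpha = NULL, beta = NULL, beta_c = NULL,
         c = cj, delta = NULL, elbo_trace = numeric(0),
         converged = FALSE, n_iter = 0L),
    class = "catmix_state")
  model <- .catmix_model(data, hyper)
  .update_params(state, model)
}

cj_clip <- function(p) pmin(pmax(p, 0), 1)

#' Initialise the variational state
#'
#' Each observation is allocated uniformly at random to one of the `K`
#' components (one-hot responsibilities); every variable starts fully
#' included (`c_j = 1`) so the model gradually de-selects variables whose
#' inclusion the data do not support. The remaining factors are completed by
#' one conjugate parameter pass. The same seed reproduces the state exactly.
#'
#' @param data a `catmix_data` object.
#' @param hyper a `catmix_hyper` object with `K >= 2`.
#' @param seed integer RNG seed.
#' @return An object of class `catmix_state`.
#' @export
initialise_state <- function(data, hyper, seed) {
  stopifnot(inherits(data, "catmix_data"), inherits(hyper, "catmix_hyper"))
  if (hyper$K < 2L)
    stop("`K` must be at least 2 for a mixture fit", call. = FALSE)
  set.seed(as.integer(seed))
  N <- nrow(data$data)
  z <- sample.int(hyper$K, N, replace = TRUE)
  resp <- matrix(0, N, hyper$K)
  resp[cbind(seq_len(N), z)] <- 1
  state_from_responsibilities(data, hyper, resp)
}

# One full coordinate-ascent cycle in fixed order:
# (i) q(pi), (ii) q(Phi), (iii) q(delta), (iv) q(gamma), (v) q(Z).
# `update_selection = FALSE` freezes step (iv), leaving c at its current
# value; the remaining steps are still exact coordinate updates, so the
# ELBO stays non-decreasing either way.
.sweep <- function(state, model, update_selection = TRUE) {
  hyper <- model$hyper
  K <- ncol(state$resp)
  state <- .update_params(state, model)          # (i)-(iii)
  elogphi <- .elog_phi(state, model)

  if (hyper$variable_selection && update_selection) {   # (iv)
    d1 <- state$delta[, 1L]; d2 <- state$delta[, 2L]
    dgsum <- digamma(d1 + d2)
    elog_delta <- digamma(d1) - dgsum
    elog_1mdelta <- digamma(d2) - dgsum
    Tj <- numeric(model$P)
    for (l in seq_len(model$Lmax))
      Tj <- Tj + colSums(model$ind[[l]] * (state$resp %*% elogphi[[l]]))
    eta <- elog_delta - elog_1mdelta + Tj - model$U
    state$c <- stats::plogis(eta)
  }

  elogpi <- digamma(state$alpha) - digamma(sum(state$alpha))  # (v)
  logrho <- matrix(elogpi, model$N, K, byrow = TRUE)
  cm <- state$c
  for (l in seq_len(model$Lmax))
    logrho <- logrho + model$ind[[l]] %*% t(elogphi[[l]] * matrix(cm, K, model$P, byrow = TRUE))
  nullpart <- as.vector(
    Reduce(`+`, lapply(seq_len(model$Lmax),
                       function(l) model$ind[[l]] %*% ((1 - cm) * model$logphi0[, l]))))
  logrho <- logrho + nullpart
  if (any(!is.finite(logrho)))
    stop("non-finite responsibilities encountered", call. = FALSE)
  mx <- logrho[cbind(seq_len(model$N), max.col(logrho, ties.method = "first"))]
  r <- exp(logrho - mx)
  state$resp <- r / rowSums(r)
  state
}

#' One coordinate-ascent sweep
#'
#' Runs a single full cycle of the variational updates in the fixed order
#' q(pi), q(Phi), q(delta), q(gamma), q(Z). Expectations of log-Dirichlet
#' variables use the digamma function. Exposed mainly for inspection and
#' testing; [catmix_fit()] drives the same update with cached indicator
#' matrices.
#'
#' @param state a `catmix_state` object.
#' @param data,null,hyper the dataset, null model and hyperparameters.
#' @return The updated `catmix_state`.
#' @export
cavi_sweep <- function(state, data, null, hyper) {
  model <- .catmix_model(data, hyper, null)
  .sweep(state, model)
}

.xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

.compute_elbo <- function(state, model, components = FALSE) {
  hyper <- model$hyper
  K <- ncol(state$resp)
  a0 <- hyper$alpha0
  elogphi <- .elog_phi(state, model)
  betasum <- Reduce(`+`, state$beta)
  parts <- c(data = 0, allocation = 0, weights = 0, phi = 0,
             gamma = 0, delta = 0)

  # expected log-likelihood of the data: cluster part weighted by c_j,
  # null part by (1 - c_j)
  datc <- numeric(model$P)
  for (l in seq_len(model$Lmax)) {
    counts <- crossprod(state$resp, model$ind[[l]])
    datc <- datc + colSums(counts * elogphi[[l]])
  }
  parts["data"] <- sum(state$c * datc) + sum((1 - state$c) * model$U)

  # allocations: E[log p(Z | pi)] + H[q(Z)]
  elogpi <- digamma(state$alpha) - digamma(sum(state$alpha))
  nk <- colSums(state$resp)
  parts["allocation"] <- sum(nk * elogpi) - sum(.xlogx(state$resp))

  # mixture weights: Dirichlet prior minus variational Dirichlet
  parts["weights"] <- lgamma(K * a0) - K * lgamma(a0) + sum((a0 - 1) * elogpi) -
    (lgamma(sum(state$alpha)) - sum(lgamma(state$alpha)) +
       sum((state$alpha - 1) * elogpi))

  # category probabilities, per component x variable
  sum_elogphi <- Reduce(`+`, elogphi)                       # K x P
  prior_const <- lgamma(model$L * model$eps) - model$L * lgamma(model$eps)
  qphi <- lgamma(betasum)
  for (l in seq_len(model$Lmax)) {
    v <- model$colmask[[l]]
    qphi[, v] <- qphi[, v] - lgamma(state$beta[[l]][, v, drop = FALSE]) +
      (state$beta[[l]][, v, drop = FALSE] - 1) * elogphi[[l]][, v, drop = FALSE]
  }
  parts["phi"] <- K * sum(prior_const) +
    sum(sweep(sum_elogphi, 2L, model$eps - 1, "*")) - sum(qphi)

  if (hyper$variable_selection) {
    d1 <- state$delta[, 1L]; d2 <- state$delta[, 2L]
    dgsum <- digamma(d1 + d2)
    elog_delta <- digamma(d1) - dgsum
    elog_1mdelta <- digamma(d2) - dgsum
    cj <- state$c
    # selection indicators: E[log p(gamma | delta)] + H[q(gamma)]
    parts["gamma"] <- sum(cj * elog_delta + (1 - cj) * elog_1mdelta) -
      sum(.xlogx(cj) + .xlogx(1 - cj))
    # Beta hyperprior minus variational Beta
    a <- hyper$a
    parts["delta"] <- sum(-lbeta(a, a) + (a - 1) * (elog_delta + elog_1mdelta)) -
      sum(-lbeta(d1, d2) + (d1 - 1) * elog_delta + (d2 - 1) * elog_1mdelta)
  }
  elbo <- sum(parts)
  if (!is.finite(elbo)) stop("non-finite ELBO", call. = FALSE)
  if (components) parts else elbo
}

#' Evidence lower bound of the current variational state
#'
#' Computes `E_q[log p(X, Z, pi, Phi, gamma, delta)] - E_q[log q]` as a sum
#' of named contributions (data term including the null-model part for
#' de-selected variables, allocation term, Dirichlet prior/entropy terms for
#' the weights and category probabilities, and Bernoulli/Beta terms for the
#' selection layer). Non-decreasing across [cavi_sweep()] calls.
#'
#' @inheritParams cavi_sweep
#' @param components logical; return the named contributions instead of
#'   their sum?
#' @return A finite scalar, or a named numeric vector when
#'   `components = TRUE`.
#' @export
compute_elbo <- function(state, data, null, hyper, components = FALSE) {
  model <- .catmix_model(data, hyper, null)
  .compute_elbo(state, model, components = components)
}

#' Fit the variational categorical mixture
#'
#' Alternates coordinate-ascent sweeps with ELBO evaluation until the
#' relative ELBO change drops below `tol` or `max_iter` sweeps have run.
#' Component labels are arbitrary (label switching across seeds is
#' expected); superfluous components are emptied by the sparse weight prior,
#' so `n_nonempty` estimates the number of clusters.
#'
#' With variable selection, the optimisation is staged: every variable stays
#' fully included (`c_j = 1`) while the allocation and parameter updates
#' organise the clustering, and the selection updates are enabled once the
#' selection-frozen ELBO has stabilised (relative change below
#' `burnin_tol`, at most `burnin_max` sweeps). Running all coordinates from
#' the first sweep lets the complexity penalty of the still-unstructured
#' clustering de-select variables prematurely, and a de-selected variable
#' cannot re-enter because its count-weighted Dirichlet factor has already
#' collapsed to the prior; the staging removes that hysteresis. Every sweep
#' in both phases is an exact coordinate-ascent step, so the ELBO trace is
#' non-decreasing across the whole fit, including at the switch.
#'
#' @param data a `catmix_data` object.
#' @param hyper a `catmix_hyper` object.
#' @param seed integer seed for the random initial allocation.
#' @param tol relative ELBO change declaring convergence (default 5e-8).
#' @param max_iter maximum number of sweeps (default 2000). Non-convergence
#'   yields a warning and `converged = FALSE`, not an error.
#' @param burnin_tol relative ELBO change at which the selection updates are
#'   switched on (default 1e-5); ignored without variable selection.
#' @param burnin_max latest sweep at which selection updates start
#'   (default 100).
#' @return An object of class `catmix_fit`: list with `state`,
#'   `map_partition` (argmax cluster labels), `n_nonempty`, `selected`
#'   (`c_j > 0.5`), `c`, `final_elbo`, `elbo_trace`, `seed`, `converged`,
#'   `n_iter`, `hyper`.
#' @export
catmix_fit <- function(data, hyper, seed, tol = 5e-8, max_iter = 2000L,
                       burnin_tol = 1e-5, burnin_max = 100L) {
  stopifnot(inherits(data, "catmix_data"), inherits(hyper, "catmix_hyper"))
  model <- .catmix_model(data, hyper)
  state <- initialise_state(data, hyper, seed)
  trace <- numeric(0)
  selecting <- !hyper$variable_selection  # FALSE = selection still frozen
  for (it in seq_len(max_iter)) {
    state <- tryCatch(.sweep(state, model, update_selection = selecting),
                      error = function(e)
      stop(sprintf("numerical failure at iteration %d: %s", it,
                   conditionMessage(e)), call. = FALSE))
    elbo <- tryCatch(.compute_elbo(state, model), error = function(e)
      stop(sprintf("numerical failure at iteration %d: %s", it,
                   conditionMessage(e)), call. = FALSE))
    trace <- c(trace, elbo)
    rel <- if (it >= 2L) abs(trace[it] - trace[it - 1L]) / abs(trace[it]) else Inf
    if (!selecting) {
      if (rel < burnin_tol || it >= burnin_max) selecting <- TRUE
    } else if (rel < tol) {
      state$converged <- TRUE
      break
    }
  }
  state$n_iter <- length(trace)
  state$elbo_trace <- trace
  if (!state$converged)
    warning(sprintf("not converged after %d sweeps (rel. change %.2e)",
                    max_iter, abs(diff(utils::tail(trace, 2))) / abs(trace[length(trace)])),
            call. = FALSE)
  mp <- map_partition(state)
  structure(
    list(state = state, map_partition = mp$labels, n_nonempty = mp$n_nonempty,
         selected = state$c > 0.5, c = state$c,
         final_elbo = trace[length(trace)], elbo_trace = trace,
         seed = as.integer(seed), converged = state$converged,
         n_iter = state$n_iter, hyper = hyper,
         row_ids = data$row_ids, column_ids = data$column_ids),
    class = "catmix_fit")
}

#' Hard cluster assignment from responsibilities
#'
#' @param state a `catmix_state` object (or anything with a `resp` matrix).
#' @return List with `labels` (argmax component per observation, ties broken
#'   by lowest index) and `n_nonempty` (number of distinct labels).
#' @export
map_partition <- function(state) {
  resp <- if (is.list(state)) state$resp else state
  labels <- max.col(resp, ties.method = "first")
  list(labels = labels, n_nonempty = length(unique(labels)))
}

#' @export
print.catmix_fit <- function(x, ...) {
  cat(sprintf("Variational categorical mixture fit (K = %d)\n", x$hyper$K))
  cat(sprintf("  non-empty clusters : %d\n", x$n_nonempty))
  cat(sprintf("  ELBO               : %.4f after %d sweeps (%s)\n",
              x$final_elbo, x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  if (x$hyper$variable_selection)
    cat(sprintf("  selected variables : %d / %d\n",
                sum(x$selected), length(x$selected)))
  invisible(x)
}
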