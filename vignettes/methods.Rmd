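---
title: "Variational categorical mixtures with variable selection and model averaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variational categorical mixtures with variable selection and model averaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`catmixvi` clusters N observations of P categorical variables (binary data
is the two-category case) with a Bayesian finite mixture. Each component k
carries a categorical distribution per variable, with probabilities
$\Phi_{kj} = (\phi_{kj1}, \dots, \phi_{kjL_j})$, and the observation density
is $\sum_k \pi_k \prod_j \phi_{kj x_j}$.

Two design features address the two questions practitioners actually have —
*how many clusters?* and *which variables matter?*

**Overfitted mixture.** The number of components K is set above the number
of clusters expected, and the symmetric Dirichlet prior on the weights uses
a concentration $\alpha_0 < 1$ (default 0.01). Under this sparse prior,
posterior mass concentrates on configurations in which superfluous
components are empty, so the number of non-empty components after fitting
estimates the number of clusters. There is no model-selection loop over K.

**Feature saliency.** A binary indicator $\gamma_j$ per variable switches
variable j between cluster-specific parameters $\Phi_{kj}$ ($\gamma_j = 1$)
and a single null distribution $\Phi_{0j}$ shared by all clusters
($\gamma_j = 0$):
$$f(x_n \mid \text{cluster } k) = \prod_j f_j(x_{nj} \mid \Phi_{kj})^{\gamma_j}
  \, f_j(x_{nj} \mid \Phi_{0j})^{1-\gamma_j}.$$
$\gamma_j \mid \delta_j \sim \text{Bernoulli}(\delta_j)$ with
$\delta_j \sim \text{Beta}(a, a)$, so the prior inclusion probability is
itself inferred. $\Phi_{0j}$ is precomputed once as the
$\varepsilon_j$-smoothed empirical category frequencies of column j — the
posterior-mean estimate under the no-clustering assumption — and held fixed;
this keeps the de-selected branch a constant lookup rather than another set
of variational factors.

Priors: $\pi \sim \text{Dir}(\alpha_0)$,
$\phi_{kj} \sim \text{Dir}(\varepsilon_j)$ (symmetric, default
$\varepsilon_j = 1/L_j$, i.e. no preferred category), $a = 2$ by default.

## Inference

The posterior is approximated by a mean-field product
$q(Z)\,q(\pi)\,q(\Phi)\,q(\gamma)\,q(\delta)$ optimised by coordinate
ascent on the evidence lower bound (ELBO). All factors are conjugate, so
each update is closed-form; expectations of log-Dirichlet variables use the
digamma function. One sweep updates, in fixed order:

1. $q(\pi) = \text{Dir}(\alpha_k)$, $\alpha_k = \alpha_0 + \sum_n r_{nk}$;
2. $q(\phi_{kj}) = \text{Dir}(\beta_{kjl})$,
   $\beta_{kjl} = \varepsilon_j + c_j \sum_n r_{nk}\,\mathbb{1}[x_{nj} = l]$,
   where $c_j = E[\gamma_j]$;
3. $q(\delta_j) = \text{Beta}(a + c_j,\, a + 1 - c_j)$;
4. $c_j = \sigma(\eta_j)$ with
   $\eta_j = E[\log \delta_j] - E[\log(1-\delta_j)]
   + \sum_{n,k} r_{nk} E[\log \phi_{kj x_{nj}}]
   - \sum_n \log \phi_{0j x_{nj}}$;
5. $\log r_{nk} \propto E[\log \pi_k]
   + \sum_j c_j E[\log \phi_{kj x_{nj}}]
   + \sum_j (1 - c_j) \log \phi_{0j x_{nj}}$, rows renormalised.

Initialisation allocates each observation uniformly at random to one of the
K components (one-hot responsibilities) and sets every $c_j = 1$, after
which one parameter pass completes the state. Convergence is declared when
the relative ELBO change falls below `tol` (default 5e-8, at most
`max_iter = 2000` sweeps); both are configurable. The ELBO is evaluated
after every sweep and the trace is checked to be non-decreasing in the test
suite — any decrease is a hard failure, since each step is an exact
coordinate maximisation.

### Staged variable selection

Running all five updates from the first sweep makes selection collapse: at
a random initial allocation no cluster structure exists, so for every
variable the digamma complexity penalty of K half-empty Dirichlet factors
outweighs the (nonexistent) signal, $\eta_j$ goes negative, and $c_j$
drops. The collapse is irreversible because step 2 weights the counts by
$c_j$: once $c_j$ is small, $q(\phi_{kj})$ shrinks to its prior, the
cluster branch fits even worse, and $\eta_j$ falls further. Measured on
N = 1000, P = 100 data with 75% informative variables, the simultaneous
scheme retains 28/75 informative variables and reaches ARI 0.13.

`catmix_fit` therefore stages the optimisation: the $q(\gamma)$ update is
frozen at its initial $c_j = 1$ — all variables included — until the
selection-frozen ELBO has stabilised (relative change below
`burnin_tol = 1e-5`, at most `burnin_max = 100` sweeps), and is then
switched on. Holding one coordinate fixed keeps every sweep an exact
ascent step, so the ELBO trace is non-decreasing across the whole fit,
including at the switch. After the switch, variables whose cluster-specific
fit beats the null retain $c_j \approx 1$ and noise variables fall below
0.5; the same run on the data above reaches ARI ≈ 0.75 and per-run
selection F1 ≈ 0.9. The burn-in controls are exposed as arguments; the
defaults were fixed once from the optimisation behaviour, not from any
downstream benchmark.

### Numerical details

Per-category indicator matrices are precomputed once per fit, so a sweep is
a handful of dense N×P / N×K matrix products. Responsibilities are computed
by log-sum-exp; zero responsibilities contribute zero entropy
($0 \log 0 = 0$); `beta` cells for categories a variable does not have are
masked out of every sum. MAP labels use `max.col` with lowest-index tie
breaking, for determinism. With `K = 1` and selection off, q is the exact
posterior and the ELBO equals the closed-form Dirichlet-categorical log
evidence — the test suite asserts agreement to 1e-6 against an
independently coded closed form.

## Model averaging

Variational optima depend on initialisation, so a single run can land in a
poor local optimum and typically fragments clusters (the per-run non-empty
count overestimates the truth). The averaging layer runs M independently
seeded fits (default M = 25; run m uses seed `base_seed + m`) and combines
them through the N×N co-clustering matrix
$P_{ij} = \tfrac1M \sum_m \mathbb{1}[z_i^{(m)} = z_j^{(m)}]$,
the frequency with which two observations share a cluster — the analogue of
an MCMC posterior similarity matrix, immune to label switching.

Two summarisers turn P into one partition:

* **Medvedovic**: complete-linkage agglomeration on the distance $1 - P$,
  cut at height 0.99 (so any pair that essentially never separates is
  grouped). The cut height is a convention, exposed as an argument.
* **Minimum expected VoI** (default, `voi_complete`): candidates are the
  cuts of the $1-P$ dendrogram (complete or average linkage) into
  $1, \dots, K$ clusters; each candidate c is scored by the Jensen lower
  bound on the posterior-expected variation of information,
  $$\frac1N \sum_i \Big[\log_2 |C_i| + \log_2 \sum_j P_{ij}
    - 2 \log_2 \sum_{j \in C_i} P_{ij}\Big],$$
  (base-2 logs, a scale convention only) and the minimiser is returned,
  ties to fewer clusters. Searching dendrogram cuts rather than the full
  partition lattice is the standard tractable restriction.

Selected variables are summarised by the proportion of runs with final
$c_j > 0.5$, thresholded strictly at $\tau$ (default 0.95; 0.5 is the
common alternative). Strict thresholding means "in more than 95% of runs".

## The synthetic-data generator

`generate_dataset` plants K_true clusters with sizes drawn uniformly in a
range and rescaled to sum to N by largest-remainder rounding (every cluster
kept non-empty). For binary data, each informative (cluster, variable) cell
gets an independent Beta(1, 5) success probability — sparse events whose
rates differ across clusters, the regime of mutation indicators and similar
'omics data; each noise variable gets a single Beta(1, 5) probability shared
by all clusters, so it is exactly uninformative about membership (the test
suite verifies chi-squared tests against the labels reject at the nominal
rate). For L > 2 categories, probability vectors are symmetric Dirichlet(1)
draws; this flat choice is a configurable neutral default.

What the generator does *not* emulate: correlated variables, missing
entries, cluster-size imbalance beyond the stated range, and
category-sparsity patterns of real assays. Passing the simulation-based
checks therefore demonstrates correctness of the inference and averaging
machinery under the generating model, not performance on any particular
real dataset.

## Experiment scale and defaults

The replicated experiments in the tests and in `scripts/acceptance.R` use
3 datasets × 25 runs per scenario at N = 1000, P = 100, K_init = 30 — the
package's desk-scale choice for routine verification; a single fit takes
about a second, a full scenario a couple of minutes. `run_experiment`
exposes the dataset count, run count, sub-ensemble sizes and thresholds so
larger replications are one call away.

Defaults worth knowing: $\alpha_0 = 0.01$ (sparse regime; anything well
below 1 behaves similarly), $a = 2$, $\varepsilon_j = 1/L_j$, M = 25,
`voi_complete`, $\tau = 0.95$. `K_init` has no default: set it comfortably
above the number of clusters you expect (2–3×).

## Known limitations

* Selection probabilities for noise variables converge near 0.5 rather
  than 0 in single runs (the spurious-association bonus and the complexity
  penalty nearly cancel); the across-run threshold is what removes them
  reliably. Interpret single-run `selected` vectors with care.
* The minimum-expected-VoI search is restricted to dendrogram cuts; the
  reported score is a lower bound on the expected VoI, not the exact value.
* Complete-data only: missing entries are rejected, not imputed.
* The consensus partition occasionally keeps one or two small spurious
  clusters (cluster counts within ±1 of truth in the tested scenarios).
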