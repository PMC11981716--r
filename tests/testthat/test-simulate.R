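test_that("designs validate their size constraints", {
  expect_error(simulation_design(N = 100, K_true = 10, cluster_sizes = c(20, 50)),
               "infeasible")
  expect_error(simulation_design(relevant_fraction = 0), "relevant_fraction")
  d <- simulation_design(N = 60, K_true = 3, cluster_sizes = c(10, 30), seed = 2)
  expect_s3_class(d, "catmix_design")
})

test_that("generation is reproducible and respects the design", {
  d <- simulation_design(N = 80, P = 12, K_true = 4, cluster_sizes = c(10, 40),
                         relevant_fraction = 0.5, seed = 9)
  s1 <- generate_dataset(d)
  s2 <- generate_dataset(d)
  expect_identical(s1$dataset$data, s2$dataset$data)
  expect_identical(s1$true_labels, s2$true_labels)
  expect_equal(sum(s1$sizes), 80)
  expect_true(all(s1$sizes >= 1))
  expect_equal(sum(s1$relevant), 6)
  expect_equal(length(s1$true_labels), 80)
  full <- generate_dataset(simulation_design(N = 40, P = 5, K_true = 2,
                                             cluster_sizes = c(10, 30),
                                             relevant_fraction = 1, seed = 1))
  expect_true(all(full$relevant))
})

test_that("noise variables share one probability vector across clusters", {
  s <- generate_dataset(simulation_design(N = 50, P = 10, K_true = 3,
                                          cluster_sizes = c(10, 25),
                                          relevant_fraction = 0.5, seed = 4))
  for (j in which(!s$relevant)) {
    pj <- s$generating_probs[, j, ]
    expect_true(all(apply(pj, 2, function(col) max(col) - min(col)) < 1e-12))
  }
  # relevant variables differ across clusters almost surely
  rel_var <- vapply(which(s$relevant),
                    function(j) max(apply(s$generating_probs[, j, ], 2,
                                          function(col) max(col) - min(col))),
                    0)
  expect_true(all(rel_var > 0))
})

test_that("success probabilities concentrate around the Beta(1,5) mean", {
  s <- generate_dataset(simulation_design(N = 10, P = 400, K_true = 8,
                                          cluster_sizes = c(1, 2),
                                          relevant_fraction = 1, seed = 6))
  # 8 x 400 independent Beta(1,5) draws: mean within Monte-Carlo error of 1/6
  expect_equal(mean(s$generating_probs[, , 2]), 1 / 6, tolerance = 0.01)
})

test_that("three-category generation uses flat Dirichlet cell probabilities", {
  s <- generate_dataset(simulation_design(N = 30, P = 6, K_true = 2,
                                          cluster_sizes = c(10, 20),
                                          n_categories = 3, seed = 5))
  expect_equal(s$dataset$n_categories, rep(3L, 6))
  expect_true(all(abs(apply(s$generating_probs, c(1, 2), sum) - 1) < 1e-12))
  expect_true(all(s$dataset$data %in% 0:2))
})

test_that("noise columns are independent of the true labels at the nominal rate", {
  # chi-squared association tests between labels and noise columns should
  # reject at roughly the nominal 5% level
  pvals <- unlist(lapply(1:12, function(seed) {
    s <- generate_dataset(simulation_design(N = 200, P = 10, K_true = 3,
                                            cluster_sizes = c(40, 100),
                                            relevant_fraction = 0.3,
                                            seed = 500 + seed))
    vapply(which(!s$relevant), function(j)
      suppressWarnings(stats::chisq.test(table(s$true_labels,
                                               s$dataset$data[, j]))$p.value),
      0)
  }))
  expect_gt(length(pvals), 50)
  rej <- mean(pvals < 0.05)
  expect_lt(rej, 0.12)
  expect_gt(mean(pvals), 0.35)   # roughly uniform p-values
})

test_that("experiments are reproducible and degenerate gracefully at M = 1", {
  design <- simulation_design(N = 60, P = 10, K_true = 3,
                              cluster_sizes = c(10, 30), seed = 1)
  r1 <- run_experiment(design, K_init = 6, M = 1, n_datasets = 1,
                       base_seed = 5, variable_selection = FALSE)
  # with one run the consensus is that run's MAP partition
  ari_run <- r1$value[r1$unit == "run" & r1$metric == "ari"]
  ari_cons <- r1$value[r1$unit == "consensus" & r1$metric == "ari"]
  expect_equal(ari_cons, ari_run)
  r2 <- run_experiment(design, K_init = 6, M = 1, n_datasets = 1,
                       base_seed = 5, variable_selection = FALSE)
  expect_identical(r1, r2)
})
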