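test_that("reference subtraction inverts a zero-noise mixture algebraically", {
  set.seed(41)
  G <- 50; n <- 15
  genes <- paste0("g", 1:G)
  prof <- compartment_profiles(
    matrix(rnorm(G, 3, 1), G, 1, dimnames = list(genes, NULL)),
    rnorm(G, 3, 1), rnorm(G, 3, 1))
  f <- matrix(rgamma(3 * n, c(8, 3, 2)), n, 3, byrow = TRUE)
  f <- compartment_fractions(f[, 1] / rowSums(f), f[, 2] / rowSums(f),
                             f[, 3] / rowSums(f),
                             sample_ids = paste0("s", 1:n))
  obs <- reconstruct_mixture(prof, f, rep(1L, n))
  ref_i <- stats::setNames(prof$immune, genes)
  ref_s <- stats::setNames(prof$stromal, genes)

  est <- two_step_cancer_profile(obs, ref_i, ref_s, f, rescale = "none")
  expect_lt(max(abs(est - matrix(prof$cancer[, 1], G, n))), 1e-6)
  expect_equal(attr(est, "n_floored"), 0L)

  # pure cancer samples: output equals the observed matrix
  f_pure <- compartment_fractions(rep(1, n), rep(0, n), rep(0, n),
                                  sample_ids = paste0("s", 1:n))
  est_pure <- two_step_cancer_profile(obs, ref_i, ref_s, f_pure,
                                      rescale = "none")
  expect_equal(est_pure, obs, ignore_attr = TRUE)

  # random instance vs direct element-wise arithmetic (median rescaling on)
  obs_n <- obs + matrix(rnorm(G * n, 0, 0.1), G, n)
  est_n <- two_step_cancer_profile(obs_n, ref_i, ref_s, f)
  s <- median(exp(obs_n)) / median(c(exp(ref_i), exp(ref_s)))
  num <- exp(obs_n) - outer(exp(ref_i) * s, f[, "immune"]) -
    outer(exp(ref_s) * s, f[, "stromal"])
  num <- pmax(num, 1e-6 * median(exp(obs_n)))
  oracle <- log(sweep(num, 2, f[, "cancer"], "/"))
  expect_equal(est_n, oracle, ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(
    two_step_cancer_profile(obs, ref_i[-1], ref_s, f, rescale = "none"),
    "missing genes")
})

test_that("quantile normalization equalizes column distributions", {
  set.seed(5)
  x <- matrix(rnorm(200, 0, c(1, 5)), 20, 10)
  q <- quantile_normalize(x)
  sorted <- apply(q, 2, sort)
  expect_lt(max(apply(sorted, 1, function(v) diff(range(v)))), 1e-9)
})

test_that("baseline clustering co-clusters identical samples and recovers clean structure", {
  sim <- quick_sim(n_genes = 120, n_samples = 30, seed = 19)
  obs <- sim$observed
  obs_dup <- cbind(obs, obs[, 1])
  colnames(obs_dup) <- c(colnames(obs), "dup")
  lab <- baseline_cluster(obs_dup, 3, mode = "bulk", config = fast_control(seed = 19))
  expect_equal(lab[31], lab[1])

  # two-step on the exactly subtracted cancer matrix recovers truth
  cancer_mat <- two_step_cancer_profile(
    obs, stats::setNames(sim$true_profiles$immune, rownames(obs)),
    stats::setNames(sim$true_profiles$stromal, rownames(obs)),
    sim$true_fractions, rescale = "none")
  lab2 <- baseline_cluster(cancer_mat, 3, mode = "two_step",
                           config = fast_control(seed = 19))
  expect_equal(clustering_accuracy(sim$true_assignment, lab2)$accuracy, 1)
})

test_that("best-permutation accuracy matches exhaustive search for K <= 5", {
  set.seed(55)
  for (K in 2:5) {
    for (rep in 1:5) {
      n <- 40
      truth <- sample(K, n, replace = TRUE)
      est <- truth
      flip <- sample(n, 12)
      est[flip] <- sample(K, 12, replace = TRUE)
      est <- sample(K)[est]  # random relabeling
      got <- clustering_accuracy(truth, est)
      expect_equal(got$accuracy, oracle_best_permutation_accuracy(truth, est))
    }
  }
})

test_that("recovery metrics are exact for truth and invariant to label permutation", {
  sim <- quick_sim(n_genes = 80, n_samples = 24, seed = 61)
  fit <- structure(
    list(profiles = sim$true_profiles, fractions = sim$true_fractions,
         assignment = sim$true_assignment, n_subtypes = 3L,
         gene_ids = rownames(sim$observed), sample_ids = colnames(sim$observed)),
    class = "declust_fit")
  ev <- evaluate_recovery(sim, fit)
  expect_equal(ev$fraction_accuracy, 1)
  expect_equal(ev$clustering_accuracy, 1)
  expect_equal(ev$ari, 1)
  expect_equal(ev$profile_accuracy, 1)

  # permuted labels (with matching profile columns) leave all metrics at 1
  perm <- c(2L, 3L, 1L)
  fit_p <- fit
  fit_p$assignment <- perm[sim$true_assignment]
  fit_p$profiles <- compartment_profiles(
    sim$true_profiles$cancer[, order(perm)],
    sim$true_profiles$immune, sim$true_profiles$stromal)
  ev_p <- evaluate_recovery(sim, fit_p)
  expect_equal(ev_p$clustering_accuracy, 1)
  expect_equal(ev_p$profile_accuracy, 1)

  # profile accuracy unaffected by adding a constant to both sides
  fit_c <- fit
  fit_c$profiles <- compartment_profiles(sim$true_profiles$cancer + 5,
                                         sim$true_profiles$immune + 5,
                                         sim$true_profiles$stromal + 5)
  expect_equal(evaluate_recovery(sim, fit_c)$profile_accuracy, 1)
})

test_that("random assignments score near chance for balanced classes", {
  set.seed(101)
  n <- 6000
  truth <- sample(3, n, replace = TRUE)
  est <- sample(3, n, replace = TRUE)
  acc <- clustering_accuracy(truth, est)$accuracy
  expect_lt(abs(acc - 1 / 3), 0.03)
})

test_that("replicate summaries recompute their averages", {
  sim <- quick_sim(n_genes = 60, n_samples = 20, seed = 71)
  fit <- structure(
    list(profiles = sim$true_profiles, fractions = sim$true_fractions,
         assignment = sim$true_assignment, n_subtypes = 3L,
         gene_ids = rownames(sim$observed), sample_ids = colnames(sim$observed)),
    class = "declust_fit")
  reports <- list(evaluate_recovery(sim, fit),
                  evaluate_recovery(sim, sample(3, 20, replace = TRUE)))
  summ <- recovery_summary(reports)
  expect_equal(nrow(summ$per_replicate), 2)
  expect_equal(unname(summ$means["clustering_accuracy"]),
               mean(summ$per_replicate$clustering_accuracy))
})
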