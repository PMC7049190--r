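test_that("single-subtype fit recovers profiles from exact one-subtype mixtures", {
  set.seed(21)
  G <- 60; n <- 30
  # compartment profiles share a per-gene base, as real compartments do;
  # keeps every true value inside the optimizer's per-gene box
  base <- rnorm(G, 3, 1)
  prof <- compartment_profiles(matrix(base + rnorm(G, 0, 0.4), G, 1),
                               base + rnorm(G, 0, 0.4),
                               base + rnorm(G, 0, 0.4))
  f <- matrix(rgamma(3 * n, c(10, 4, 3)), n, 3, byrow = TRUE)
  f <- compartment_fractions(f[, 1] / rowSums(f), f[, 2] / rowSums(f),
                             f[, 3] / rowSums(f))
  obs <- reconstruct_mixture(prof, f, rep(1L, n))
  fit <- fit_single_subtype(obs, f, fast_control(optim_maxit = 20000,
                                                 optim_factr = 1))
  expect_lt(max(abs(fit$cancer[, 1] - prof$cancer[, 1])), 1e-3)
  expect_lt(max(abs(fit$immune - prof$immune)), 1e-2)
  expect_equal(compute_mse(obs, fit, f, rep(1L, n)), 0, tolerance = 1e-6)
})

test_that("single-subtype fit on pure-cancer samples returns the row means", {
  set.seed(22)
  obs <- matrix(rnorm(50, 3, 1), 10, 5,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  f <- compartment_fractions(rep(1, 5), rep(0, 5), rep(0, 5))
  fit <- fit_single_subtype(obs, f)
  expect_equal(unname(fit$cancer[, 1]), unname(rowMeans(obs)), tolerance = 1e-5)
  expect_setequal(attr(fit, "unidentifiable_compartments"),
                  c("immune", "stromal"))
  # descent: fitted objective no worse than the row-mean initialization
  init <- compartment_profiles(matrix(rowMeans(obs), 10, 1),
                               rowMeans(obs), rowMeans(obs))
  expect_lte(compute_mse(obs, fit, f, rep(1L, 5)),
             compute_mse(obs, init, f, rep(1L, 5)) + 1e-9)
})

test_that("residual K-means initialization separates blobs and is well-behaved", {
  ctl <- fast_control(seed = 4)
  # unequal blob sizes so the size-based label renumbering is unambiguous
  r <- matrix(rnorm(40, 0, 0.05), 4, 10)
  r[, 7:10] <- r[, 7:10] + 3

  expect_identical(init_subtypes(r, 1, ctl), rep(1L, 10))
  expect_error(init_subtypes(r, 11, ctl), "more subtypes")

  lab <- init_subtypes(r, 2, ctl)
  expect_identical(lab[1:6], rep(1L, 6))
  expect_identical(lab[7:10], rep(2L, 4))

  # matches the exhaustive minimum within-cluster SS 2-partition on <= 10 samples
  best_ss <- Inf; best_split <- NULL
  for (m in 1:(2^9)) {
    grp <- as.logical(bitwAnd(m, 2^(0:9)) > 0)
    if (!any(grp) || all(grp)) next
    ss <- sum(scale(t(r[, grp, drop = FALSE]), scale = FALSE)^2) +
      sum(scale(t(r[, !grp, drop = FALSE]), scale = FALSE)^2)
    if (ss < best_ss) { best_ss <- ss; best_split <- grp }
  }
  expect_true(all(lab[best_split] == lab[best_split][1]) &&
                all(lab[!best_split] == lab[!best_split][1]) &&
                lab[best_split][1] != lab[!best_split][1])

  # permuting samples permutes labels consistently
  perm <- sample(10)
  lab_p <- init_subtypes(r[, perm], 2, ctl)
  expect_identical(lab_p, lab[perm])
})

test_that("profile optimization recovers truth and respects the empty-subtype contract", {
  sim <- quick_sim(n_genes = 100, n_samples = 30, seed = 13,
                   compartment_sd = 0.4)
  obs <- sim$observed
  truth <- sim$true_profiles
  ctl <- fast_control(seed = 13, optim_maxit = 3000, optim_factr = 1e3)
  # warm start away from truth
  warm <- compartment_profiles(truth$cancer + 0.3, truth$immune + 0.3,
                               truth$stromal - 0.3)
  fit <- optimize_profiles(obs, sim$true_fractions, sim$true_assignment,
                           warm, ctl)
  expect_lt(mean(abs(fit$cancer - truth$cancer)), 0.01)
  expect_lt(mean(abs(fit$immune - truth$immune)), 0.05)
  # descent vs warm start
  expect_lte(compute_mse(obs, fit, sim$true_fractions, sim$true_assignment),
             compute_mse(obs, warm, sim$true_fractions, sim$true_assignment) + 1e-9)

  # an absent subtype keeps its warm-start column
  asg <- sim$true_assignment
  asg[asg == 3L] <- 1L
  fit2 <- optimize_profiles(obs, sim$true_fractions, asg, warm, ctl)
  expect_identical(attr(fit2, "empty_subtypes"), 3L)
  expect_equal(fit2$cancer[, 3], warm$cancer[, 3])
})

test_that("reassignment equals per-sample brute force with lowest-index ties", {
  st <- tiny_state()
  obs <- reconstruct_mixture(st$profiles, st$fractions, st$assignment)

  # exact match -> original labels back
  expect_identical(reassign_subtypes(obs, st$profiles, st$fractions),
                   st$assignment)

  # exact tie between subtypes -> lowest index
  prof_tie <- compartment_profiles(
    cbind(st$profiles$cancer[, 1], st$profiles$cancer[, 2],
          st$profiles$cancer[, 1]),
    st$profiles$immune, st$profiles$stromal)
  lab <- reassign_subtypes(obs, prof_tie, st$fractions)
  expect_identical(lab, c(1L, 2L, 1L))

  # random instances vs brute force, K up to 5
  set.seed(77)
  for (rep in 1:10) {
    K <- sample(2:5, 1); G <- 12; n <- 20
    prof <- compartment_profiles(matrix(rnorm(G * K, 2, 1), G, K),
                                 rnorm(G, 2, 1), rnorm(G, 2, 1))
    f <- matrix(rgamma(3 * n, 2), n, 3)
    f <- compartment_fractions(f[, 1] / rowSums(f), f[, 2] / rowSums(f),
                               f[, 3] / rowSums(f))
    o <- reconstruct_mixture(prof, f, sample(K, n, replace = TRUE)) +
      matrix(rnorm(G * n, 0, 0.5), G, n)
    lab <- reassign_subtypes(o, prof, f)
    brute <- vapply(seq_len(n), function(j) {
      sse <- vapply(seq_len(K), function(k) {
        sum((o[, j] - reconstruct_mixture(prof, f[j, , drop = FALSE], k))^2)
      }, numeric(1))
      which.min(sse)
    }, integer(1))
    expect_identical(lab, brute)
  }
})

test_that("reassignment is equivariant under subtype label permutation", {
  set.seed(31)
  K <- 4; G <- 15; n <- 12
  prof <- compartment_profiles(matrix(rnorm(G * K, 2, 1), G, K),
                               rnorm(G, 2, 1), rnorm(G, 2, 1))
  f <- matrix(rgamma(3 * n, 2), n, 3)
  f <- compartment_fractions(f[, 1] / rowSums(f), f[, 2] / rowSums(f),
                             f[, 3] / rowSums(f))
  o <- matrix(rnorm(G * n, 2, 1), G, n,
              dimnames = list(paste0("g", 1:G), paste0("s", 1:n)))
  lab <- reassign_subtypes(o, prof, f)
  perm <- c(3L, 1L, 4L, 2L)  # prof column k becomes column perm[k]
  prof_p <- compartment_profiles(prof$cancer[, order(perm)], prof$immune,
                                 prof$stromal)
  lab_p <- reassign_subtypes(o, prof_p, f)
  expect_identical(lab_p, perm[lab])
})

test_that("inner loop descends and recovers zero-noise subtype structure", {
  sim <- quick_sim(n_genes = 150, n_samples = 36, seed = 8)
  ctl <- fast_control(seed = 8)

  # K = 1 degenerates to a single profile fit
  st1 <- run_inner_loop(sim$observed, sim$true_fractions, 1, ctl)
  expect_identical(st1$assignment, rep(1L, 36))

  st <- run_inner_loop(sim$observed, sim$true_fractions, 3, ctl)
  expect_true(all(diff(st$trace) <= 1e-9))
  acc <- clustering_accuracy(sim$true_assignment, st$assignment)
  expect_equal(acc$accuracy, 1)
})

test_that("fraction optimization recovers truth and stays on the simplex", {
  sim <- quick_sim(n_genes = 150, n_samples = 25, seed = 17)
  truth <- sim$true_profiles
  # perturbed warm start
  warm <- project_simplex_rows <- sim$true_fractions
  warm[, "immune"] <- pmin(warm[, "immune"] + 0.15, 1)
  warm <- warm / rowSums(warm)
  fr <- optimize_fractions(sim$observed, truth, sim$true_assignment, warm,
                           fast_control(seed = 17))
  expect_lt(max(abs(fr - sim$true_fractions)), 1e-3)
  expect_true(all(fr >= 0 & fr <= 1))
  expect_equal(unname(rowSums(fr)), rep(1, 25), tolerance = 1e-8)

  # a sample identical to the immune profile is called (nearly) all-immune
  obs2 <- cbind(sim$observed[, 1:4], immune_like = truth$immune)
  warm2 <- rbind(warm[1:4, ], c(1 / 3, 1 / 3, 1 / 3))
  rownames(warm2) <- colnames(obs2)
  fr2 <- optimize_fractions(obs2, truth, c(sim$true_assignment[1:4], 1L),
                            warm2, fast_control(seed = 17))
  expect_gt(fr2["immune_like", "immune"], 0.98)
})

test_that("full fit is deterministic and recovers zero-noise ground truth", {
  sim <- quick_sim(n_genes = 150, n_samples = 40, seed = 23)
  ctl <- fast_control(seed = 23, max_outer_iter = 6)
  fit1 <- suppressWarnings(run_declust(sim$observed, sim$markers, 3, ctl))
  fit2 <- suppressWarnings(run_declust(sim$observed, sim$markers, 3, ctl))
  expect_identical(fit1$fractions, fit2$fractions)
  expect_identical(fit1$assignment, fit2$assignment)
  expect_identical(fit1$profiles$cancer, fit2$profiles$cancer)

  expect_true(all(diff(fit1$history$outer) <= 1e-9))
  ev <- evaluate_recovery(sim, fit1)
  expect_equal(ev$clustering_accuracy, 1)
  expect_gt(ev$fraction_accuracy, 0.99)
})
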