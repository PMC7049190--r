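# Small programmatic fixtures shared across test files.

# A tiny hand-built model state with easily checkable arithmetic.
tiny_state <- function() {
  genes <- c("g1", "g2", "g3")
  cancer <- cbind(subtype_1 = log(c(2, 3, 5)), subtype_2 = log(c(6, 1, 2)))
  rownames(cancer) <- genes
  profiles <- compartment_profiles(cancer, log(c(4, 2, 1)), log(c(8, 5, 3)))
  fractions <- compartment_fractions(c(0.5, 1, 0.2), c(0.25, 0, 0.5),
                                     c(0.25, 0, 0.3),
                                     sample_ids = c("s1", "s2", "s3"))
  assignment <- c(1L, 2L, 1L)
  list(profiles = profiles, fractions = fractions, assignment = assignment)
}

# Quick small simulation; zero noise and subtype-shared non-cancer profiles
# unless overridden.
quick_sim <- function(n_genes = 200, n_samples = 40, n_subtypes = 3,
                      noise_level = 0, seed = 42, ...) {
  simulate_dataset(simulation_config(
    n_genes = n_genes, n_samples = n_samples, n_subtypes = n_subtypes,
    noise_level = noise_level, noncancer_subtype_specific = FALSE,
    n_marker_genes = 15, seed = seed, ...))
}

fast_control <- function(seed = 42, ...) {
  declust_control(seed = seed, ...)
}

# Exhaustive best-permutation clustering agreement (oracle for K <= 5).
oracle_best_permutation_accuracy <- function(truth, estimate) {
  K <- max(truth, estimate)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  best <- 0
  for (p in perms(seq_len(K))) {
    best <- max(best, mean(p[estimate] == truth))
  }
  best
}
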