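# Synthetic bulk-tumor mixture generator with full ground truth.
#
# Emulates the benchmark design: K cancer-subtype reference profiles with
# moderate pairwise rank correlation, near-identical immune and stromal
# profiles across subtypes, subtype-conditional compartment fractions on the
# simplex, and log-normal or negative-binomial noise on the mixture.

#' Simulation configuration
#'
#' All log-scale quantities are in natural-log units. Defaults reflect a
#' bladder-cancer-like three-subtype cohort: a dominant luminal-like
#' subtype, a basal-like subtype, and a rare neuronal-like subtype;
#' moderate pairwise similarity between cancer subtype profiles and
#' near-identical non-cancer profiles across subtypes; mean tumor purity
#' between 0.55 and 0.70 with Dirichlet spread typical of bulk cohorts.
#'
#' @param n_genes,n_samples Dimensions of the simulated matrix.
#' @param n_subtypes Number of cancer subtypes K.
#' @param subtype_proportions Simplex over K; expected share of samples per
#'   subtype.
#' @param target_cancer_profile_correlation Mean pairwise Spearman
#'   correlation between cancer subtype profiles (achieved within ~0.02 by
#'   bisection on the perturbation scale).
#' @param target_noncancer_profile_correlation Floor for the mutual Spearman
#'   correlation between the subtype-specific immune (and stromal) profile
#'   variants.
#' @param fraction_means K x 3 matrix of per-subtype mean (cancer, immune,
#'   stromal) fractions; default purity rises across subtypes from 0.55 to
#'   0.70 with the remainder split 60/40 between immune and stromal.
#' @param fraction_concentration Dirichlet concentration; larger means
#'   tighter fractions around the subtype mean.
#' @param noise_model `"lognormal"` (additive Gaussian on the log mixture)
#'   or `"negative_binomial"` (counts with mean equal to the linear mixture,
#'   then `log(count + 1)`).
#' @param noise_level Log-scale noise standard deviation (lognormal model).
#' @param nb_dispersion Negative-binomial size parameter (moderate
#'   overdispersion by default).
#' @param n_marker_genes Designated marker genes per non-cancer compartment.
#' @param marker_logfc Log-units by which a marker gene exceeds the other
#'   compartments' profiles in its own compartment.
#' @param noncancer_subtype_specific Simulate subtype-specific immune and
#'   stromal profile variants (the fitted model itself assumes none); when
#'   `FALSE` the variants are identical and the zero-noise mixture is an
#'   exact realization of the fitted model.
#' @param base_mean,base_sd Mean and SD of the shared log-scale base profile
#'   common to all compartments.
#' @param compartment_sd SD of the compartment-specific log-scale deviation
#'   from the shared base (controls how related cancer, immune, and stromal
#'   profiles are to each other).
#' @param seed Integer seed; the generator is fully deterministic given the
#'   configuration.
#' @return A list of class `declust_sim_config`.
#' @export
simulation_config <- function(n_genes = 1500L, n_samples = 100L,
                              n_subtypes = 3L,
                              subtype_proportions = NULL,
                              target_cancer_profile_correlation = 0.87,
                              target_noncancer_profile_correlation = 0.98,
                              fraction_means = NULL,
                              fraction_concentration = 25,
                              noise_model = c("lognormal", "negative_binomial"),
                              noise_level = 0.3,
                              nb_dispersion = 10,
                              n_marker_genes = 50L,
                              marker_logfc = 2,
                              noncancer_subtype_specific = TRUE,
                              base_mean = 4, base_sd = 1,
                              compartment_sd = 1,
                              seed = 1L) {
  noise_model <- match.arg(noise_model)
  K <- as.integer(n_subtypes)
  if (is.null(subtype_proportions)) {
    subtype_proportions <- if (K == 3L) c(0.5, 0.35, 0.15) else rep(1 / K, K)
  }
  if (length(subtype_proportions) != K || abs(sum(subtype_proportions) - 1) > 1e-8) {
    stop("subtype_proportions must be a simplex over n_subtypes")
  }
  if (is.null(fraction_means)) {
    purity <- if (K == 1L) 0.65 else seq(0.55, 0.70, length.out = K)
    fraction_means <- cbind(cancer = purity, immune = 0.6 * (1 - purity),
                            stromal = 0.4 * (1 - purity))
  }
  fraction_means <- as.matrix(fraction_means)
  if (nrow(fraction_means) != K || ncol(fraction_means) != 3L ||
      any(fraction_means <= 0) || any(abs(rowSums(fraction_means) - 1) > 1e-8)) {
    stop("fraction_means must be a K x 3 matrix of positive rows summing to 1")
  }
  colnames(fraction_means) <- c("cancer", "immune", "stromal")
  stopifnot(n_genes >= 10L, n_samples >= 2L, noise_level >= 0,
            n_marker_genes >= 3L, nb_dispersion > 0,
            target_cancer_profile_correlation > 0,
            target_cancer_profile_correlation < 1,
            target_noncancer_profile_correlation > 0,
            target_noncancer_profile_correlation < 1,
            2L * n_marker_genes < n_genes)
  structure(
    list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
         n_subtypes = K, subtype_proportions = subtype_proportions,
         target_cancer_profile_correlation = target_cancer_profile_correlation,
         target_noncancer_profile_correlation = target_noncancer_profile_correlation,
         fraction_means = fraction_means,
         fraction_concentration = fraction_concentration,
         noise_model = noise_model, noise_level = noise_level,
         nb_dispersion = nb_dispersion,
         n_marker_genes = as.integer(n_marker_genes),
         marker_logfc = marker_logfc,
         noncancer_subtype_specific = noncancer_subtype_specific,
         base_mean = base_mean, base_sd = base_sd,
         compartment_sd = compartment_sd,
         seed = as.integer(seed)),
    class = "declust_sim_config"
  )
}

# Scale s of per-subtype perturbations (base + s * z_k) chosen by bisection
# so the realized mean pairwise Spearman correlation hits `target`.
#' @keywords internal
.calibrate_perturbation <- function(base, z, target, tol = 0.01) {
  realized <- function(s) {
    E <- base + s * z
    cc <- stats::cor(E, method = "spearman")
    mean(cc[upper.tri(cc)])
  }
  lo <- 0; hi <- 0.5
  while (realized(hi) > target && hi < 64) hi <- hi * 2
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    if (realized(mid) > target) lo <- mid else hi <- mid
    if (hi - lo < 1e-6) break
  }
  s <- (lo + hi) / 2
  if (abs(realized(s) - target) > max(tol, 0.05)) {
    stop("could not reach the requested profile correlation target")
  }
  s
}

#' Generate compartment reference profiles and marker sets
#'
#' Draws a shared log-scale base profile, adds independent
#' compartment-specific deviations (so cancer, immune, and stromal profiles
#' are related but distinct, as in real tissue), then perturbs the cancer
#' base per subtype with a scale calibrated by bisection to the target
#' pairwise Spearman correlation. Immune and stromal subtype variants are
#' calibrated the same way at the (much higher) non-cancer target. Marker
#' genes are overexpressed in their own compartment by `marker_logfc` log
#' units above every other compartment.
#'
#' @param config A [simulation_config()].
#' @return A list with `profiles` (a [compartment_profiles()] holding the K
#'   cancer profiles and the across-variant average immune and stromal
#'   profiles — the evaluation ground truth), `immune_variants`,
#'   `stromal_variants` (genes x K), `markers` (a [marker_set()]), and
#'   `realized_correlations`.
#' @export
generate_reference_profiles <- function(config) {
  stopifnot(inherits(config, "declust_sim_config"))
  G <- config$n_genes; K <- config$n_subtypes
  gene_ids <- sprintf("gene_%05d", seq_len(G))
  withr::with_seed(config$seed, {
    g <- stats::rnorm(G, config$base_mean, config$base_sd)
    cb <- g + stats::rnorm(G, 0, config$compartment_sd)
    ib <- g + stats::rnorm(G, 0, config$compartment_sd)
    sb <- g + stats::rnorm(G, 0, config$compartment_sd)
    zc <- matrix(stats::rnorm(G * K), G, K)
    zi <- matrix(stats::rnorm(G * K), G, K)
    zs <- matrix(stats::rnorm(G * K), G, K)
    marker_idx <- sample.int(G, 2L * config$n_marker_genes)
  })
  if (K > 1L) {
    s_c <- .calibrate_perturbation(cb, zc, config$target_cancer_profile_correlation)
    cancer <- cb + s_c * zc
  } else {
    cancer <- matrix(cb, G, 1L)
  }
  if (config$noncancer_subtype_specific && K > 1L) {
    s_i <- .calibrate_perturbation(ib, zi, config$target_noncancer_profile_correlation)
    s_s <- .calibrate_perturbation(sb, zs, config$target_noncancer_profile_correlation)
    imm_var <- ib + s_i * zi
    str_var <- sb + s_s * zs
  } else {
    imm_var <- matrix(ib, G, K)
    str_var <- matrix(sb, G, K)
  }

  imm_idx <- marker_idx[seq_len(config$n_marker_genes)]
  str_idx <- marker_idx[config$n_marker_genes + seq_len(config$n_marker_genes)]
  # markers: own-compartment value exceeds every other compartment by the
  # configured log fold change, identical across subtype variants
  imm_val <- pmax(apply(cancer[imm_idx, , drop = FALSE], 1L, max),
                  apply(str_var[imm_idx, , drop = FALSE], 1L, max)) +
    config$marker_logfc
  imm_var[imm_idx, ] <- imm_val
  str_val <- pmax(apply(cancer[str_idx, , drop = FALSE], 1L, max),
                  apply(imm_var[str_idx, , drop = FALSE], 1L, max)) +
    config$marker_logfc
  str_var[str_idx, ] <- str_val

  rownames(cancer) <- rownames(imm_var) <- rownames(str_var) <- gene_ids
  colnames(cancer) <- paste0("subtype_", seq_len(K))
  cc <- if (K > 1L) stats::cor(cancer, method = "spearman") else matrix(1, 1, 1)
  ci <- stats::cor(imm_var, method = "spearman")
  cs <- stats::cor(str_var, method = "spearman")
  list(
    profiles = compartment_profiles(cancer, rowMeans(imm_var), rowMeans(str_var)),
    immune_variants = imm_var, stromal_variants = str_var,
    markers = marker_set(gene_ids[imm_idx], gene_ids[str_idx]),
    realized_correlations = list(
      cancer = if (K > 1L) mean(cc[upper.tri(cc)]) else 1,
      immune = if (K > 1L) mean(ci[upper.tri(ci)]) else 1,
      stromal = if (K > 1L) mean(cs[upper.tri(cs)]) else 1)
  )
}

#' Draw subtype labels and compartment fractions
#'
#' Labels are sampled per the configured subtype proportions; each sample's
#' fractions are Dirichlet draws around its subtype's mean vector with the
#' configured concentration.
#'
#' @param config A [simulation_config()].
#' @return A list with `fractions` (samples x 3, on the simplex) and
#'   `assignment` (integer labels).
#' @export
sample_fractions <- function(config) {
  stopifnot(inherits(config, "declust_sim_config"))
  n <- config$n_samples; K <- config$n_subtypes
  withr::with_seed(config$seed + 1L, {
    assignment <- sample.int(K, n, replace = TRUE,
                             prob = config$subtype_proportions)
    f <- matrix(NA_real_, n, 3L, dimnames = list(NULL, c("cancer", "immune", "stromal")))
    for (j in seq_len(n)) {
      alpha <- config$fraction_concentration * config$fraction_means[assignment[j], ]
      draw <- stats::rgamma(3L, shape = alpha, rate = 1)
      f[j, ] <- draw / sum(draw)
    }
  })
  rownames(f) <- sprintf("sample_%03d", seq_len(n))
  list(fractions = f, assignment = as.integer(assignment))
}

#' Simulate a bulk-tumor mixture dataset with full ground truth
#'
#' Builds the linear-scale mixture of the (subtype-resolved) compartment
#' profiles weighted by the sampled fractions, then adds noise: additive
#' Gaussian on the log scale (lognormal model) or negative-binomial counts
#' with mean equal to the linear mixture, observed as `log(count + 1)`.
#'
#' @param config A [simulation_config()].
#' @return An object of class `declust_sim`: `observed` (genes x samples log
#'   matrix), `true_profiles`, `true_fractions`, `true_assignment`,
#'   `markers`, `mixture_log` (the exact noise-free log mixture),
#'   `immune_variants`, `stromal_variants`, and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "declust_sim_config"))
  refs <- generate_reference_profiles(config)
  fa <- sample_fractions(config)
  G <- config$n_genes
  asg <- fa$assignment
  M <- exp(refs$profiles$cancer)[, asg, drop = FALSE] *
    rep(fa$fractions[, "cancer"], each = G) +
    exp(refs$immune_variants)[, asg, drop = FALSE] *
    rep(fa$fractions[, "immune"], each = G) +
    exp(refs$stromal_variants)[, asg, drop = FALSE] *
    rep(fa$fractions[, "stromal"], each = G)
  mixture_log <- log(M)
  dimnames(mixture_log) <- list(rownames(refs$profiles$cancer),
                                rownames(fa$fractions))
  observed <- withr::with_seed(config$seed + 2L, {
    if (config$noise_model == "lognormal") {
      if (config$noise_level > 0) {
        mixture_log + matrix(stats::rnorm(length(M), 0, config$noise_level),
                             nrow = G)
      } else {
        mixture_log
      }
    } else {
      counts <- matrix(stats::rnbinom(length(M), mu = as.vector(M),
                                      size = config$nb_dispersion), nrow = G)
      log(counts + 1)
    }
  })
  dimnames(observed) <- dimnames(mixture_log)
  structure(
    list(observed = observed, true_profiles = refs$profiles,
         true_fractions = fa$fractions, true_assignment = fa$assignment,
         markers = refs$markers, mixture_log = mixture_log,
         immune_variants = refs$immune_variants,
         stromal_variants = refs$stromal_variants,
         realized_correlations = refs$realized_correlations,
         config = config),
    class = "declust_sim"
  )
}

#' Simulate a batch of replicate datasets
#'
#' Replicates share the configuration but advance the seed, mirroring a
#' benchmark design with many datasets per (sample size, noise level)
#' combination.
#'
#' @param config A [simulation_config()]; its seed anchors the batch.
#' @param n_datasets Number of replicates (default 20).
#' @return A list of `declust_sim` objects.
#' @export
simulate_batch <- function(config, n_datasets = 20L) {
  stopifnot(inherits(config, "declust_sim_config"), n_datasets >= 1L)
  lapply(seq_len(n_datasets), function(i) {
    cfg <- config
    cfg$seed <- config$seed + (i - 1L) * 101L
    simulate_dataset(cfg)
  })
}

#' @export
print.declust_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated dataset: %d genes x %d samples, K = %d, %s noise (level %.3g)\n",
    nrow(x$observed), ncol(x$observed), x$config$n_subtypes,
    x$config$noise_model, x$config$noise_level))
  invisible(x)
}
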