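# Comparator pipelines (plain K-means on bulk data; reference-subtraction
# two-step clustering) and ground-truth recovery metrics.

#' Two-step cancer expression profile by reference subtraction
#'
#' Given reference immune and stromal profiles and per-sample fractions,
#' removes the non-cancer signal from each bulk sample in linear scale:
#' `E_cancer = (o_mix - refE_immune * f_immune - refE_stromal * f_stromal) /
#' f_cancer`. With `rescale = "median"` the reference matrix is first
#' multiplied by one scalar so its median matches the median of the
#' linear-scale mixture (for references on a different scale than the data);
#' `"none"` uses the references as given. Negative subtracted values are
#' floored at a small positive epsilon before returning to log scale; the
#' number of floored entries is recorded in attribute `"n_floored"`.
#'
#' @param observed Genes x samples log expression matrix.
#' @param ref_immune,ref_stromal Per-gene log-scale reference profiles,
#'   named by gene identifier (must cover every gene in `observed`).
#' @param fractions Samples x 3 fraction matrix; every cancer fraction must
#'   be at least 0.01.
#' @param rescale `"median"` (default) or `"none"`.
#' @return Genes x samples matrix of log-scale estimated cancer expression.
#' @export
two_step_cancer_profile <- function(observed, ref_immune, ref_stromal,
                                    fractions, rescale = c("median", "none")) {
  rescale <- match.arg(rescale)
  validate_expression_matrix(observed)
  validate_fractions(fractions)
  if (any(fractions[, "cancer"] < 0.01)) {
    stop("cancer fractions below 0.01; subtraction is unstable")
  }
  genes <- rownames(observed)
  if (!is.null(names(ref_immune))) {
    if (!all(genes %in% names(ref_immune)) || !all(genes %in% names(ref_stromal))) {
      stop("reference profiles are missing genes present in the observed matrix")
    }
    ref_immune <- ref_immune[genes]
    ref_stromal <- ref_stromal[genes]
  } else if (length(ref_immune) != nrow(observed) ||
             length(ref_stromal) != nrow(observed)) {
    stop("reference profiles are missing genes present in the observed matrix")
  }
  G <- nrow(observed)
  olin <- exp(observed)
  ru <- exp(ref_immune); rv <- exp(ref_stromal)
  if (rescale == "median") {
    s <- stats::median(olin) / stats::median(c(ru, rv))
    ru <- ru * s; rv <- rv * s
  }
  num <- olin - tcrossprod(ru, fractions[, "immune"]) -
    tcrossprod(rv, fractions[, "stromal"])
  eps <- 1e-6 * stats::median(olin)
  n_floored <- sum(num < eps)
  num <- pmax(num, eps)
  out <- log(num / rep(fractions[, "cancer"], each = G))
  dimnames(out) <- dimnames(observed)
  attr(out, "n_floored") <- n_floored
  out
}

#' Quantile-normalize the columns of a matrix
#'
#' Maps every column onto the mean empirical distribution (via
#' [limma::normalizeQuantiles()]), so all columns share identical sorted
#' values.
#'
#' @param x Numeric matrix.
#' @return The normalized matrix.
#' @export
quantile_normalize <- function(x) {
  out <- limma::normalizeQuantiles(x)
  dimnames(out) <- dimnames(x)
  out
}

#' Baseline K-means subtyping
#'
#' `mode = "bulk"` clusters the samples of the given matrix directly;
#' `mode = "two_step"` quantile-normalizes the columns first (intended for
#' the subtracted cancer matrix from [two_step_cancer_profile()]). K-means
#' settings (seed, restarts) are shared with the main optimizer; labels are
#' renumbered by descending cluster size.
#'
#' @param x Genes x samples matrix to cluster.
#' @param n_subtypes Number of clusters K (at most the sample count).
#' @param mode `"bulk"` or `"two_step"`.
#' @param config A [declust_control()] object.
#' @return Integer vector of labels in 1..K.
#' @export
baseline_cluster <- function(x, n_subtypes, mode = c("bulk", "two_step"),
                             config = declust_control()) {
  mode <- match.arg(mode)
  if (n_subtypes > ncol(x)) stop("more subtypes than samples")
  if (mode == "two_step") x <- quantile_normalize(x)
  init_subtypes(x, n_subtypes, config)
}

# Best bijection between estimated and true labels, maximizing agreement on
# the K x K contingency table via maximum-weight bipartite matching (counts
# are integers, so the matching is exact). Returns perm with perm[e] = true
# label matched to estimated label e.
#' @keywords internal
.best_label_permutation <- function(truth, estimate) {
  K <- max(truth, estimate)
  ct <- table(factor(truth, levels = seq_len(K)),
              factor(estimate, levels = seq_len(K)))
  ct <- matrix(as.numeric(ct), K, K)
  # +1 keeps zero-count pairings as edges so a perfect matching always exists
  g <- igraph::graph_from_biadjacency_matrix(ct + 1, weighted = TRUE)
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  truth_to_est <- m$matching[seq_len(K)] - K
  perm <- integer(K)
  perm[truth_to_est] <- seq_len(K)
  list(perm = perm, agreement = sum(ct[cbind(perm, seq_len(K))]))
}

#' Clustering accuracy under the best label permutation
#'
#' The maximum over label permutations of the agreement fraction between
#' true and estimated labels (optimal assignment on the contingency table),
#' together with the adjusted Rand index.
#'
#' @param truth,estimate Integer label vectors of equal length.
#' @return A list with `accuracy`, `ari`, and `mapping` (true label matched
#'   to each estimated label).
#' @export
clustering_accuracy <- function(truth, estimate) {
  truth <- as.integer(truth); estimate <- as.integer(estimate)
  if (length(truth) != length(estimate)) stop("label vectors differ in length")
  bp <- .best_label_permutation(truth, estimate)
  list(accuracy = bp$agreement / length(truth),
       ari = mclust::adjustedRandIndex(truth, estimate),
       mapping = bp$perm)
}

#' Recovery metrics against simulation ground truth
#'
#' Compares an estimate to the ground truth of a [simulate_dataset()]
#' result. For a full `declust_fit`: `fraction_accuracy` is the mean over
#' the three compartments of the across-sample Pearson correlation between
#' true and estimated fractions; `clustering_accuracy` is the
#' best-permutation agreement (plus adjusted Rand index); and
#' `profile_accuracy` is the mean over compartments of the across-gene
#' Pearson correlation between true and estimated profiles, with the cancer
#' subtype columns matched by the same label permutation and averaged
#' before entering the compartment mean. Spearman analogues are reported
#' for diagnostics. A bare label vector (e.g. from [baseline_cluster()])
#' yields clustering metrics only.
#'
#' @param truth A `declust_sim` object.
#' @param estimate A `declust_fit` object or an integer label vector.
#' @return A list of class `declust_eval` with the metrics above.
#' @export
evaluate_recovery <- function(truth, estimate) {
  stopifnot(inherits(truth, "declust_sim"))
  if (is.numeric(estimate) && is.null(dim(estimate))) {
    ca <- clustering_accuracy(truth$true_assignment, estimate)
    return(structure(list(fraction_accuracy = NA_real_,
                          clustering_accuracy = ca$accuracy, ari = ca$ari,
                          profile_accuracy = NA_real_, mapping = ca$mapping),
                     class = "declust_eval"))
  }
  stopifnot(inherits(estimate, "declust_fit"))
  if (!identical(rownames(truth$observed), estimate$gene_ids)) {
    stop("gene sets of truth and estimate differ")
  }
  ft <- truth$true_fractions; fe <- estimate$fractions
  if (nrow(ft) != nrow(fe)) stop("sample counts of truth and estimate differ")
  frac_cor <- vapply(colnames(ft), function(cc) {
    stats::cor(ft[, cc], fe[, cc])
  }, numeric(1))

  ca <- clustering_accuracy(truth$true_assignment, estimate$assignment)

  pt <- truth$true_profiles; pe <- estimate$profiles
  Ke <- pe$n_subtypes
  cancer_cors <- vapply(seq_len(Ke), function(e) {
    t_lab <- ca$mapping[e]
    if (t_lab >= 1L && t_lab <= pt$n_subtypes) {
      stats::cor(pt$cancer[, t_lab], pe$cancer[, e])
    } else NA_real_
  }, numeric(1))
  comp_cors <- c(cancer = mean(cancer_cors, na.rm = TRUE),
                 immune = stats::cor(pt$immune, pe$immune),
                 stromal = stats::cor(pt$stromal, pe$stromal))
  comp_cors_sp <- c(
    cancer = mean(vapply(seq_len(Ke), function(e) {
      t_lab <- ca$mapping[e]
      if (t_lab >= 1L && t_lab <= pt$n_subtypes) {
        stats::cor(pt$cancer[, t_lab], pe$cancer[, e], method = "spearman")
      } else NA_real_
    }, numeric(1)), na.rm = TRUE),
    immune = stats::cor(pt$immune, pe$immune, method = "spearman"),
    stromal = stats::cor(pt$stromal, pe$stromal, method = "spearman"))

  structure(
    list(fraction_accuracy = mean(frac_cor),
         fraction_cor = frac_cor,
         clustering_accuracy = ca$accuracy, ari = ca$ari,
         profile_accuracy = mean(comp_cors),
         profile_cor = comp_cors,
         profile_cor_spearman = comp_cors_sp,
         mapping = ca$mapping),
    class = "declust_eval"
  )
}

#' Summarize recovery metrics over replicates
#'
#' @param reports A list of `declust_eval` objects.
#' @return A list with `per_replicate` (data frame) and `means`.
#' @export
recovery_summary <- function(reports) {
  df <- do.call(rbind, lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(replicate = i,
               fraction_accuracy = r$fraction_accuracy,
               clustering_accuracy = r$clustering_accuracy,
               ari = r$ari,
               profile_accuracy = r$profile_accuracy)
  }))
  list(per_replicate = df,
       means = colMeans(df[, -1L, drop = FALSE], na.rm = TRUE))
}

#' @export
print.declust_eval <- function(x, ...) {
  cat(sprintf(
    "Recovery: fractions %.3f | clustering %.3f (ARI %.3f) | profiles %.3f\n",
    x$fraction_accuracy, x$clustering_accuracy, x$ari, x$profile_accuracy))
  invisible(x)
}
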