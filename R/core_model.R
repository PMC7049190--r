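# Core mixture model: each bulk sample is a convex combination, on the
# natural (linear) expression scale, of one cancer-subtype profile and the
# immune and stromal profiles; observation and fit happen on the log scale.

# Linear-scale mixture for given linear-scale profile components.
# A: genes x K, u/v: genes, frac: samples x 3, assignment: samples.
#' @keywords internal
.mixture_linear <- function(A, u, v, frac, assignment) {
  G <- nrow(A)
  M <- A[, assignment, drop = FALSE] * rep(frac[, "cancer"], each = G)
  M <- M + tcrossprod(u, frac[, "immune"])
  M + tcrossprod(v, frac[, "stromal"])
}

#' Reconstruct the bulk mixture implied by a model state
#'
#' Computes, for every gene and sample, the log of the linear-scale convex
#' combination of the assigned cancer-subtype profile and the immune and
#' stromal profiles, weighted by the sample's compartment fractions.
#'
#' @param profiles A [compartment_profiles()] object.
#' @param fractions Samples x 3 fraction matrix (columns cancer, immune,
#'   stromal), rows on the unit simplex.
#' @param assignment Integer vector of per-sample cancer subtype labels in
#'   1..K.
#' @param tol Simplex tolerance for `fractions`.
#' @return Genes x samples matrix of log-scale reconstructed expression.
#' @export
reconstruct_mixture <- function(profiles, fractions, assignment, tol = 1e-8) {
  stopifnot(inherits(profiles, "declust_profiles"))
  validate_fractions(fractions, tol = tol)
  assignment <- validate_assignment(assignment, profiles$n_subtypes, nrow(fractions))
  M <- .mixture_linear(exp(profiles$cancer), exp(profiles$immune),
                       exp(profiles$stromal), fractions, assignment)
  out <- log(M)
  rownames(out) <- rownames(profiles$cancer)
  colnames(out) <- rownames(fractions)
  out
}

#' Squared log-reconstruction error of a model state
#'
#' The fit objective: the sum over all genes and samples of the squared
#' difference between observed and reconstructed log expression. The
#' `"mean"` variant divides by (genes x samples) and is the quantity used by
#' the BIC for subtype-number selection.
#'
#' @inheritParams reconstruct_mixture
#' @param observed Genes x samples matrix of observed log expression.
#' @param variant `"sum"` (default, the optimization objective) or `"mean"`.
#' @return Non-negative scalar.
#' @export
compute_mse <- function(observed, profiles, fractions, assignment,
                        variant = c("sum", "mean")) {
  variant <- match.arg(variant)
  r <- compute_residuals(observed, profiles, fractions, assignment)
  s <- sum(r * r)
  if (variant == "mean") s / length(r) else s
}

#' Residual log expression
#'
#' Observed minus reconstructed log expression; the substrate for the initial
#' K-means subtype clustering.
#'
#' @inheritParams compute_mse
#' @return Genes x samples matrix of residuals.
#' @export
compute_residuals <- function(observed, profiles, fractions, assignment) {
  validate_expression_matrix(observed)
  recon <- reconstruct_mixture(profiles, fractions, assignment)
  if (!all(dim(observed) == dim(recon))) stop("observed and reconstruction dimensions differ")
  observed - recon
}

#' Remove low-variance genes
#'
#' Drops genes whose log-scale standard deviation (unbiased, n - 1
#' denominator) is below `threshold`; genes exactly at the threshold are
#' retained. Gene order is preserved.
#'
#' @param observed Genes x samples matrix of log expression.
#' @param threshold Standard-deviation cutoff, default 0.5 log units.
#' @return The filtered matrix.
#' @export
filter_low_variance_genes <- function(observed, threshold = 0.5) {
  validate_expression_matrix(observed)
  if (nrow(observed) < 1L) stop("expression matrix has no genes")
  if (ncol(observed) < 2L) stop("need at least 2 samples to compute a standard deviation")
  mu <- rowMeans(observed)
  sds <- sqrt(rowSums((observed - mu)^2) / (ncol(observed) - 1L))
  keep <- sds >= threshold
  if (!any(keep)) stop("all genes removed by the variance filter; lower the threshold")
  observed[keep, , drop = FALSE]
}
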