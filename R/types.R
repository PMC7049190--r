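#' Compartment reference profiles
#'
#' Container for the log-scale expected expression of each modeled cell
#' compartment: one profile per cancer subtype plus a single immune and a
#' single stromal profile shared across subtypes.
#'
#' @param cancer Numeric matrix, genes x K, log-scale expected expression of
#'   each cancer subtype. Row names are gene identifiers.
#' @param immune,stromal Numeric vectors of per-gene log-scale expected
#'   expression, same length and gene order as `nrow(cancer)`.
#' @return An object of class `declust_profiles` with elements `cancer`,
#'   `immune`, `stromal` and `n_subtypes`.
#' @export
compartment_profiles <- function(cancer, immune, stromal) {
  cancer <- as.matrix(cancer)
  immune <- as.numeric(immune)
  stromal <- as.numeric(stromal)
  if (length(immune) != nrow(cancer) || length(stromal) != nrow(cancer)) {
    stop("immune/stromal profile length must match nrow(cancer)")
  }
  if (!all(is.finite(cancer)) || !all(is.finite(immune)) || !all(is.finite(stromal))) {
    stop("profiles must be finite")
  }
  if (ncol(cancer) < 1L) stop("need at least one cancer subtype profile")
  structure(
    list(cancer = cancer, immune = immune, stromal = stromal,
         n_subtypes = ncol(cancer), gene_ids = rownames(cancer)),
    class = "declust_profiles"
  )
}

#' Per-sample compartment fractions
#'
#' @param cancer,immune,stromal Numeric vectors of per-sample proportions.
#' @param sample_ids Optional sample identifiers.
#' @param tol Tolerance for the simplex constraint (sum to one).
#' @return A numeric matrix, samples x 3, with columns `cancer`, `immune`,
#'   `stromal`.
#' @export
compartment_fractions <- function(cancer, immune, stromal, sample_ids = NULL,
                                  tol = 1e-8) {
  f <- cbind(cancer = as.numeric(cancer), immune = as.numeric(immune),
             stromal = as.numeric(stromal))
  if (!is.null(sample_ids)) rownames(f) <- sample_ids
  validate_fractions(f, tol = tol)
  f
}

#' @keywords internal
validate_fractions <- function(f, tol = 1e-8) {
  if (!is.matrix(f) || ncol(f) != 3L) stop("fractions must be a samples x 3 matrix")
  if (any(!is.finite(f))) stop("fractions must be finite")
  if (any(f < -tol) || any(f > 1 + tol)) stop("fractions must lie in [0, 1]")
  if (any(abs(rowSums(f) - 1) > max(tol, 1e-8))) {
    stop("fractions must sum to 1 per sample (within tolerance)")
  }
  invisible(f)
}

#' @keywords internal
validate_expression_matrix <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression matrix must be a numeric matrix")
  if (any(!is.finite(x))) stop("expression matrix must not contain missing or non-finite values")
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x))) stop("duplicate gene identifiers")
  if (!is.null(colnames(x)) && anyDuplicated(colnames(x))) stop("duplicate sample identifiers")
  invisible(x)
}

#' Immune and stromal marker gene sets
#'
#' @param immune,stromal Character vectors of gene identifiers assumed to be
#'   expressed predominantly by the immune / stromal compartment.
#' @return An object of class `declust_markers`.
#' @export
marker_set <- function(immune, stromal) {
  immune <- unique(as.character(immune))
  stromal <- unique(as.character(stromal))
  if (length(immune) == 0L || length(stromal) == 0L) stop("marker lists must be non-empty")
  structure(list(immune = immune, stromal = stromal), class = "declust_markers")
}

# Intersect marker lists with the genes of an expression matrix; enforce the
# >= 3 markers-per-class and disjointness contracts.
#' @keywords internal
match_markers <- function(markers, observed) {
  genes <- rownames(observed)
  if (is.null(genes)) stop("expression matrix must have gene identifiers as row names")
  imm <- intersect(markers$immune, genes)
  str <- intersect(markers$stromal, genes)
  both <- intersect(imm, str)
  imm <- setdiff(imm, both)
  str <- setdiff(str, both)
  if (length(imm) < 3L) stop("fewer than 3 immune marker genes found in the expression matrix")
  if (length(str) < 3L) stop("fewer than 3 stromal marker genes found in the expression matrix")
  list(immune = imm, stromal = str)
}

#' @keywords internal
validate_assignment <- function(assignment, n_subtypes, n_samples) {
  assignment <- as.integer(assignment)
  if (length(assignment) != n_samples) stop("assignment length must equal the number of samples")
  if (any(assignment < 1L) || any(assignment > n_subtypes)) {
    stop("assignment labels must lie in 1..K")
  }
  assignment
}

# Project near-simplex fraction rows back onto the simplex: clip at zero,
# renormalize to sum one.
#' @keywords internal
project_simplex3 <- function(f) {
  f <- pmax(f, 0)
  s <- rowSums(f)
  if (any(s <= 0)) stop("cannot project all-zero fraction vector onto the simplex")
  f / s
}

#' @export
print.declust_profiles <- function(x, ...) {
  cat(sprintf("Compartment profiles: %d genes, %d cancer subtype(s) + immune + stromal\n",
              nrow(x$cancer), x$n_subtypes))
  invisible(x)
}

#' @export
print.declust_markers <- function(x, ...) {
  cat(sprintf("Marker set: %d immune, %d stromal genes\n",
              length(x$immune), length(x$stromal)))
  invisible(x)
}
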