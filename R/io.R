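# File formats and run provenance: genes x samples expression tables,
# one-symbol-per-line marker lists, and result writers.

#' Read a genes x samples expression table
#'
#' Tab- or comma-delimited text with gene identifiers in the first column
#' and sample identifiers in the header. Values are converted to the
#' natural-log scale used internally: `declared_scale = "linear"` applies
#' `log(x + 1)`, `"log2"` multiplies by `log(2)`, `"natural"` takes values
#' as-is. Duplicate gene identifiers are resolved by keeping the
#' highest-variance row (with a message); duplicate sample identifiers are
#' an error.
#'
#' @param path File path.
#' @param declared_scale `"natural"`, `"log2"`, or `"linear"`.
#' @return Genes x samples numeric matrix on the natural-log scale.
#' @export
read_expression_matrix <- function(path,
                                   declared_scale = c("natural", "log2", "linear")) {
  declared_scale <- match.arg(declared_scale)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          quote = "\"", comment.char = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression table needs a gene column and at least one sample")
  gene_ids <- as.character(df[[1L]])
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers in header")
  x <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(x)) stop("non-numeric cells in the expression table")
  if (any(!is.finite(x))) stop("missing or non-finite expression values")
  rownames(x) <- gene_ids
  if (anyDuplicated(gene_ids)) {
    v <- apply(x, 1L, stats::var)
    keep <- !logical(nrow(x))
    for (g in unique(gene_ids[duplicated(gene_ids)])) {
      idx <- which(gene_ids == g)
      keep[setdiff(idx, idx[which.max(v[idx])])] <- FALSE
    }
    message(sum(!keep), " duplicate gene rows dropped (kept highest variance)")
    x <- x[keep, , drop = FALSE]
  }
  x <- switch(declared_scale,
              natural = x,
              log2 = x * log(2),
              linear = {
                if (any(x < 0)) stop("negative values in a linear-scale table")
                log(x + 1)
              })
  validate_expression_matrix(x)
  x
}

#' Read a one-symbol-per-line marker list
#'
#' Blank lines and `#` comments are skipped.
#'
#' @param path File path.
#' @return Character vector of gene identifiers.
#' @export
read_marker_list <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stop("empty marker list: ", path)
  unique(x)
}

#' Read immune and stromal marker files into a marker set
#'
#' @param immune_path,stromal_path Paths to one-symbol-per-line lists.
#' @return A [marker_set()].
#' @export
read_marker_sets <- function(immune_path, stromal_path) {
  marker_set(read_marker_list(immune_path), read_marker_list(stromal_path))
}

#' Bundled immune and stromal marker panels
#'
#' Curated panels of canonical immune (leukocyte) and stromal
#' (fibroblast / extracellular-matrix) marker genes in the style of the
#' signature sets used by expression-based tumor purity tools. Intended as a
#' sensible default for human tumor data with HGNC gene symbols; for other
#' identifier schemes supply your own lists.
#'
#' @return A [marker_set()].
#' @export
default_markers <- function() {
  read_marker_sets(
    system.file("extdata", "immune_markers.txt", package = "declust",
                mustWork = TRUE),
    system.file("extdata", "stromal_markers.txt", package = "declust",
                mustWork = TRUE))
}

#' Write fit results to a directory
#'
#' Emits `fractions.tsv` (sample, f_cancer, f_immune, f_stromal),
#' `assignment.tsv` (sample, subtype), `profiles.tsv` (gene, immune,
#' stromal, subtype_1..K), optionally `bic_curve.tsv`, and `metadata.json`
#' (seed, scaling constants, tolerances, iteration history, package
#' version). All files round-trip through [read_declust_result()].
#'
#' @param fit A `declust_fit`.
#' @param outdir Output directory (created if needed).
#' @param curve Optional `declust_bic_curve`.
#' @return Invisibly, the vector of written paths.
#' @export
write_declust_result <- function(fit, outdir, curve = NULL) {
  stopifnot(inherits(fit, "declust_fit"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  samples <- fit$sample_ids
  if (is.null(samples)) samples <- sprintf("sample_%03d", seq_along(fit$assignment))

  fr <- data.frame(sample = samples,
                   f_cancer = fit$fractions[, "cancer"],
                   f_immune = fit$fractions[, "immune"],
                   f_stromal = fit$fractions[, "stromal"])
  asg <- data.frame(sample = samples, subtype = fit$assignment)
  prof <- data.frame(gene = fit$gene_ids,
                     immune = fit$profiles$immune,
                     stromal = fit$profiles$stromal)
  prof <- cbind(prof, as.data.frame(fit$profiles$cancer))

  paths <- file.path(outdir, c("fractions.tsv", "assignment.tsv", "profiles.tsv"))
  utils::write.table(fr, paths[1L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(asg, paths[2L], sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(prof, paths[3L], sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(curve)) {
    cv <- data.frame(K = curve$k_values, mse_mean = curve$mse_values,
                     BIC = curve$bic_values)
    p <- file.path(outdir, "bic_curve.tsv")
    utils::write.table(cv, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  meta <- list(
    package_version = as.character(utils::packageVersion("declust")),
    n_subtypes = fit$n_subtypes,
    seed = fit$config$seed,
    c_immune = fit$constants$c_immune,
    c_stromal = fit$constants$c_stromal,
    objective_sum = fit$objective,
    mse_mean = fit$mse_mean,
    converged = fit$converged,
    outer_iterations = fit$history$outer_iterations,
    outer_objective_trace = fit$history$outer,
    rel_tol_inner = fit$config$rel_tol_inner,
    rel_tol_outer = fit$config$rel_tol_outer,
    max_inner_iter = fit$config$max_inner_iter,
    max_outer_iter = fit$config$max_outer_iter
  )
  mp <- file.path(outdir, "metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, mp))
}

#' Read back a result directory
#'
#' @param outdir Directory written by [write_declust_result()].
#' @return A list with `fractions`, `assignment`, `profiles`, `metadata`,
#'   and (if present) `bic_curve`.
#' @export
read_declust_result <- function(outdir) {
  rd <- function(f) utils::read.table(file.path(outdir, f), header = TRUE,
                                      sep = "\t", check.names = FALSE,
                                      stringsAsFactors = FALSE)
  out <- list(
    fractions = rd("fractions.tsv"),
    assignment = rd("assignment.tsv"),
    profiles = rd("profiles.tsv"),
    metadata = jsonlite::read_json(file.path(outdir, "metadata.json"),
                                   simplifyVector = TRUE)
  )
  bp <- file.path(outdir, "bic_curve.tsv")
  if (file.exists(bp)) out$bic_curve <- rd("bic_curve.tsv")
  out
}
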