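# Marker-based initialization of compartment fractions (step 0) and the grid
# search for the two marker-to-fraction scaling constants.

#' Marker-to-fraction scaling constants
#'
#' @param c_immune,c_stromal Positive scalars translating the (linear-scale)
#'   mean marker expression of a sample into its immune / stromal fraction.
#' @return A list of class `declust_constants`.
#' @export
scaling_constants <- function(c_immune, c_stromal) {
  if (!is.finite(c_immune) || !is.finite(c_stromal) ||
      c_immune <= 0 || c_stromal <= 0) {
    stop("scaling constants must be positive")
  }
  structure(list(c_immune = c_immune, c_stromal = c_stromal),
            class = "declust_constants")
}

# Per-sample marker scores: mean log expression of the matched markers.
#' @keywords internal
.marker_scores <- function(observed, markers) {
  m <- match_markers(markers, observed)
  list(
    immune = colMeans(observed[m$immune, , drop = FALSE]),
    stromal = colMeans(observed[m$stromal, , drop = FALSE])
  )
}

#' Initial compartment fractions from marker expression (step 0)
#'
#' Assumes immune and stromal abundance proportional to the exponentiated
#' mean log expression of the respective marker genes:
#' `f_immune = exp(marker mean) * c_immune` (stromal analogous), with the
#' cancer fraction taking up the remainder. Values off the simplex are
#' clipped at zero and renormalized; attribute `"n_clipped"` records how
#' many samples required it.
#'
#' @inheritParams run_declust
#' @param constants A [scaling_constants()] object.
#' @return Samples x 3 fraction matrix on the simplex.
#' @export
init_fractions_from_markers <- function(observed, markers, constants) {
  validate_expression_matrix(observed)
  stopifnot(inherits(constants, "declust_constants"))
  sc <- .marker_scores(observed, markers)
  fi <- exp(sc$immune) * constants$c_immune
  fs <- exp(sc$stromal) * constants$c_stromal
  fc <- 1 - fi - fs
  f <- cbind(cancer = fc, immune = fi, stromal = fs)
  rownames(f) <- colnames(observed)
  clipped <- rowSums(f < 0 | f > 1) > 0
  f <- project_simplex3(f)
  attr(f, "n_clipped") <- sum(clipped)
  f
}

# One non-iterative pass of the fit used inside the grid search: step 1
# without inner iteration (single-subtype fit, residual K-means, one profile
# pass, one reassignment) followed by one fraction optimization (step 2).
#' @keywords internal
.one_pass_objective <- function(observed, fractions, n_subtypes, config) {
  cfg_fast <- config
  cfg_fast$optim_maxit <- config$grid_optim_maxit
  cfg_fast$kmeans_restarts <- min(5L, config$kmeans_restarts)
  p1 <- fit_single_subtype(observed, fractions, cfg_fast)
  r <- compute_residuals(observed, p1, fractions, rep(1L, ncol(observed)))
  assignment <- init_subtypes(r, n_subtypes, cfg_fast)
  warm <- .profiles_from_matrix(
    cbind(p1$cancer[, rep(1L, n_subtypes), drop = FALSE], p1$immune, p1$stromal),
    rownames(observed))
  prof <- optimize_profiles(observed, fractions, assignment, warm, cfg_fast)
  assignment <- reassign_subtypes(observed, prof, fractions)
  fr <- optimize_fractions(observed, prof, assignment, fractions, cfg_fast)
  compute_mse(observed, prof, fr, assignment)
}

#' Grid search for the marker scaling constants
#'
#' The feasible values of the two constants form a constrained 2-D space
#' (every implied fraction must stay in the unit interval). Each axis spans
#' `(0, c_max]` with `c_max = 1 / max_j exp(marker mean of sample j)`, so
#' the largest implied single-compartment fraction is 1, and is discretized
#' into the 10 bin centers `c_max * (k - 0.5) / 10`. For each pair whose
#' implied fractions keep every sample's cancer fraction above the
#' feasibility floor, one non-iterative pass of the fit (step 1 without
#' inner iteration, then one fraction optimization) is scored; the pair with
#' the smallest objective wins.
#'
#' @inheritParams run_declust
#' @param n_grid Number of grid points per axis (default 10).
#' @return A list with `constants` (the winning [scaling_constants()]),
#'   `grid` (data frame of all evaluated pairs: `c_immune`, `c_stromal`,
#'   `feasible`, `objective`), and `objective` (the winning value).
#' @export
grid_search_constants <- function(observed, markers, n_subtypes,
                                  config = declust_control(), n_grid = 10L) {
  validate_expression_matrix(observed)
  if (n_subtypes < 1L) stop("n_subtypes must be >= 1")
  sc <- .marker_scores(observed, markers)
  ei <- exp(sc$immune); es <- exp(sc$stromal)
  cmax_i <- 1 / max(ei)
  cmax_s <- 1 / max(es)
  ci_grid <- cmax_i * (seq_len(n_grid) - 0.5) / n_grid
  cs_grid <- cmax_s * (seq_len(n_grid) - 0.5) / n_grid

  grid <- expand.grid(c_immune = ci_grid, c_stromal = cs_grid,
                      KEEP.OUT.ATTRS = FALSE)
  max_sum <- 1 - config$min_cancer_fraction
  grid$feasible <- vapply(seq_len(nrow(grid)), function(i) {
    max(ei * grid$c_immune[i] + es * grid$c_stromal[i]) <= max_sum
  }, logical(1))
  grid$objective <- NA_real_
  if (!any(grid$feasible)) {
    stop("no feasible scaling-constant pair on the grid; inspect the marker lists")
  }
  for (i in which(grid$feasible)) {
    cst <- scaling_constants(grid$c_immune[i], grid$c_stromal[i])
    fr <- init_fractions_from_markers(observed, markers, cst)
    grid$objective[i] <- .one_pass_objective(observed, fr, n_subtypes, config)
  }
  best <- which.min(grid$objective)
  list(
    constants = scaling_constants(grid$c_immune[best], grid$c_stromal[best]),
    grid = grid,
    objective = grid$objective[best]
  )
}
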